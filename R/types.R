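#' Construct an interaction network
#'
#' Wraps a binary symmetric adjacency matrix together with its node labels.
#' One object represents one layer of the joint model: either the
#' protein-protein interaction (PPI) network or the domain-domain
#' interaction (DDI) network.
#'
#' Entries outside \{0,1\} are binarized (`> 0` becomes 1) with a warning,
#' since the model treats each entry as a Bernoulli outcome. The diagonal is
#' forced to zero: self-interactions are not part of the model.
#'
#' @param adjacency numeric square matrix; symmetric, nonnegative.
#' @param node_ids character vector of unique node labels, one per row.
#' @param layer `"protein"` or `"domain"`.
#' @return An object of class `interaction_network` with elements
#'   `adjacency`, `node_ids`, `layer`.
#' @examples
#' A <- matrix(c(0, 1, 1, 0), 2, 2)
#' net <- interaction_network(A, c("p1", "p2"), "protein")
#' @export
interaction_network <- function(adjacency, node_ids = NULL,
                                layer = c("protein", "domain")) {
  layer <- match.arg(layer)
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be square")
  n <- nrow(adjacency)
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(n))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n)
    stop("node_ids length (", length(node_ids),
         ") does not match adjacency dimension (", n, ")")
  if (anyDuplicated(node_ids))
    stop("node_ids must be unique")
  if (any(!is.finite(adjacency)) || any(adjacency < 0))
    stop("adjacency must be finite and nonnegative")
  if (any(adjacency != 0 & adjacency != 1)) {
    warning("adjacency has entries outside {0,1}; binarizing (>0 -> 1)")
    adjacency <- (adjacency > 0) + 0
  }
  if (!isTRUE(all.equal(adjacency, t(adjacency))))
    stop("adjacency must be symmetric")
  diag(adjacency) <- 0
  dimnames(adjacency) <- list(node_ids, node_ids)
  structure(list(adjacency = adjacency, node_ids = node_ids, layer = layer),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %s layer: %d nodes, %d edges\n",
              x$layer, length(x$node_ids), sum(x$adjacency) / 2))
  invisible(x)
}

#' Construct a domain-protein association map
#'
#' The binary coupling matrix `F` with `F[x, i] = 1` iff protein `i`
#' contains domain `x`. It links the two network layers: the domain-layer
#' membership matrix is defined as `F %*% H` where `H` holds protein
#' memberships, so domain memberships are always consistent with the
#' memberships of the proteins carrying each domain.
#'
#' @param matrix binary numeric matrix, domains in rows, proteins in columns.
#' @param domain_ids,protein_ids character row/column labels.
#' @return An object of class `association_map`.
#' @export
association_map <- function(matrix, domain_ids = NULL, protein_ids = NULL) {
  matrix <- as.matrix(matrix)
  if (is.null(domain_ids)) domain_ids <- paste0("d", seq_len(nrow(matrix)))
  if (is.null(protein_ids)) protein_ids <- paste0("p", seq_len(ncol(matrix)))
  domain_ids <- as.character(domain_ids)
  protein_ids <- as.character(protein_ids)
  if (length(domain_ids) != nrow(matrix) || length(protein_ids) != ncol(matrix))
    stop("label lengths must match matrix dimensions")
  if (anyDuplicated(domain_ids) || anyDuplicated(protein_ids))
    stop("row/column labels must be unique")
  if (any(matrix != 0 & matrix != 1))
    stop("association entries must be 0 or 1")
  dimnames(matrix) <- list(domain_ids, protein_ids)
  structure(list(matrix = matrix, domain_ids = domain_ids,
                 protein_ids = protein_ids),
            class = "association_map")
}

#' @export
print.association_map <- function(x, ...) {
  cat(sprintf("<association_map> %d domains x %d proteins, %d associations\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$matrix)))
  invisible(x)
}

#' Construct a membership state
#'
#' Holds the nonnegative protein-by-cluster weight matrix `H` and the
#' per-cluster relevance variances `lambda` of the automatic relevance
#' determination prior. Domain-layer memberships are never stored: they are
#' derived on demand as `F %*% H`, which keeps the two layers consistent by
#' construction.
#'
#' @param H nonnegative numeric matrix, proteins in rows, clusters in columns.
#' @param lambda positive numeric vector, one variance per cluster column.
#' @return An object of class `membership_state` with elements `H`, `lambda`,
#'   and `K` (number of cluster columns).
#' @export
membership_state <- function(H, lambda) {
  H <- as.matrix(H)
  if (any(!is.finite(H)) || any(H < 0))
    stop("H must be finite and nonnegative")
  lambda <- as.numeric(lambda)
  if (length(lambda) != ncol(H))
    stop("lambda must have one entry per column of H")
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("all lambda_k must be positive")
  structure(list(H = H, lambda = lambda, K = ncol(H)),
            class = "membership_state")
}

#' @export
print.membership_state <- function(x, ...) {
  cat(sprintf("<membership_state> %d nodes x %d clusters, max|H| = %.4g\n",
              nrow(x$H), x$K, max(x$H)))
  invisible(x)
}

#' Model hyperparameters and run controls
#'
#' @param a shape of the inverse-gamma prior on each relevance variance
#'   (default 2).
#' @param b scale of the inverse-gamma prior. If `NULL` (default) it is
#'   resolved at use time as `b_scale * N1` where `N1` is the number of
#'   proteins; the default `b_scale = 0.25` gives the standard setting
#'   `b = N1 / 4`.
#' @param b_scale multiplier used to resolve `b` from `N1` when `b` is `NULL`.
#' @param tau membership threshold used to discretize the fitted `H`
#'   (default 0.3).
#' @param omega overlap-score threshold used when matching predicted against
#'   reference complexes (default 0.25).
#' @param tol relative objective-change stopping tolerance (default 1e-3).
#' @param max_iter iteration cap for the alternating optimization
#'   (default 500).
#' @param seed RNG seed used by stochastic steps (initialization,
#'   simulation); `NULL` leaves the RNG state alone.
#' @param eps numeric floor guarding logs and divisions (default 1e-10).
#' @param perturb magnitude of the positive perturbation added at
#'   initialization; also the range of random initial entries (default 0.01).
#' @return A list of class `mnc_hyperparams`.
#' @export
mnc_hyperparams <- function(a = 2, b = NULL, b_scale = 0.25, tau = 0.3,
                            omega = 0.25, tol = 1e-3, max_iter = 500L,
                            seed = NULL, eps = 1e-10, perturb = 0.01) {
  stopifnot(a > 0, is.null(b) || b > 0, b_scale > 0,
            tau > 0, tau < 1, omega > 0, omega <= 1,
            tol > 0, max_iter >= 1, eps > 0, perturb > 0)
  structure(list(a = a, b = b, b_scale = b_scale, tau = tau, omega = omega,
                 tol = tol, max_iter = as.integer(max_iter), seed = seed,
                 eps = eps, perturb = perturb),
            class = "mnc_hyperparams")
}

# Resolve the inverse-gamma scale: explicit b wins, else b_scale * N1.
resolve_b <- function(hp, n1) {
  if (!is.null(hp$b)) hp$b else hp$b_scale * n1
}

#' Construct a complex catalog
#'
#' An ordered, named collection of complexes (sets of node labels), used for
#' both predictions and reference sets.
#'
#' @param complexes list of character vectors (the member sets). Unnamed
#'   entries get names `C1`, `C2`, ...
#' @return An object of class `complex_catalog` (a named list of character
#'   vectors, each sorted and deduplicated).
#' @export
complex_catalog <- function(complexes = list()) {
  complexes <- lapply(complexes, function(m) sort(unique(as.character(m))))
  if (any(lengths(complexes) == 0))
    stop("complexes must be non-empty member sets")
  nm <- names(complexes)
  if (is.null(nm)) nm <- rep("", length(complexes))
  blank <- !nzchar(nm)
  nm[blank] <- paste0("C", seq_along(complexes))[blank]
  if (anyDuplicated(nm))
    stop("complex names must be unique")
  names(complexes) <- nm
  structure(complexes, class = "complex_catalog")
}

#' @export
print.complex_catalog <- function(x, ...) {
  cat(sprintf("<complex_catalog> %d complexes, sizes %s\n", length(x),
              if (length(x)) paste(range(lengths(x)), collapse = "-") else "-"))
  invisible(x)
}

#' @export
`[.complex_catalog` <- function(x, i) {
  structure(unclass(x)[i], class = "complex_catalog")
}
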