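# Alternating optimization: closed-form relevance update, multiplicative
# membership update, indicator-matrix initialization, convergence control.

#' Closed-form update of the relevance variances
#'
#' Given the current memberships, each cluster variance has a closed-form
#' minimizer of the objective:
#' `lambda_k = (2 b + sum_i H_ik^2) / (N1 + 2 a + 2)`.
#' Columns that carry little mass get small variances, which in turn shrink
#' them further on the next membership update — this is the automatic
#' relevance determination mechanism that prunes superfluous clusters.
#'
#' @param H nonnegative membership matrix (N1 x K).
#' @param hp an [mnc_hyperparams] object (supplies `a` and `b`).
#' @return Positive numeric vector of length K.
#' @export
update_lambda <- function(H, hp = mnc_hyperparams()) {
  H <- as.matrix(H)
  n1 <- nrow(H)
  b <- resolve_b(hp, n1)
  (2 * b + colSums(H^2)) / (n1 + 2 * hp$a + 2)
}

# Numerator and denominator of the multiplicative update, evaluated for every
# (i, k). All pair sums exclude self-pairs, consistent with the objective.
# Returned separately so the stationarity ratio can be inspected.
update_terms <- function(A1, A2, F_map, H, lambda, eps) {
  A1 <- if (inherits(A1, "interaction_network")) A1$adjacency else as.matrix(A1)
  W1 <- -expm1(-pmax(tcrossprod(H), eps))
  num <- (A1 / W1) %*% H
  den <- matrix(colSums(H), nrow(H), ncol(H), byrow = TRUE) - H
  if (!is.null(A2)) {
    A2 <- if (inherits(A2, "interaction_network")) A2$adjacency else
      as.matrix(A2)
    Fm <- if (inherits(F_map, "association_map")) F_map$matrix else
      as.matrix(F_map)
    G <- Fm %*% H
    W2 <- -expm1(-pmax(tcrossprod(G), eps))
    num <- num + crossprod(Fm, (A2 / W2) %*% G)
    den <- den + outer(colSums(Fm), colSums(G)) - crossprod(Fm, G)
  }
  den <- den + sweep(H, 2, 2 * lambda, "/")
  list(num = num, den = den)
}

#' One multiplicative membership update
#'
#' Applies the damped multiplicative rule
#' `H_ik <- H_ik / 2 + (H_ik / 2) * num_ik / den_ik`, where the numerator
#' gathers edge-weighted affinity ratios from both layers
#' (`sum_{j != i} A1_ij H_jk / (1 - exp(-(H H^T)_ij))` plus the analogous
#' domain-layer sum) and the denominator gathers the total membership mass
#' seen by node `i` (`sum_{j != i} H_jk` plus the domain-layer analogue)
#' plus the prior shrinkage term `H_ik / (2 lambda_k)`. All pair sums
#' exclude self-pairs, so the rule is exactly stationary at critical points
#' of [mnc_objective()]: its numerator/denominator ratio is 1 wherever the
#' objective gradient vanishes. Zero entries are absorbing and
#' nonnegativity is preserved.
#'
#' @inheritParams mnc_objective
#' @return The updated nonnegative membership matrix.
#' @export
update_H <- function(A1, A2, F_map, state, hp = mnc_hyperparams()) {
  H <- state$H
  if (any(state$lambda <= 0)) stop("all lambda_k must be positive")
  tm <- update_terms(A1, A2, F_map, H, state$lambda, hp$eps)
  H_new <- H / 2 + (H / 2) * tm$num / pmax(tm$den, hp$eps)
  if (any(apply(H_new, 2, max) < .Machine$double.xmin))
    warning("a membership column has collapsed to zero")
  H_new
}

#' Stationarity diagnostic: the multiplicative update ratio
#'
#' Returns the matrix of numerator/denominator ratios of the multiplicative
#' rule. At a stationary point every entry with positive membership has a
#' ratio of 1 (its update is a no-op); how far the ratios sit from 1 over
#' the active entries measures the remaining optimization gap.
#'
#' @inheritParams mnc_objective
#' @return Matrix of ratios, same shape as `state$H`.
#' @export
mnc_multiplier_ratio <- function(A1, A2, F_map, state,
                                 hp = mnc_hyperparams()) {
  tm <- update_terms(A1, A2, F_map, state$H, state$lambda, hp$eps)
  tm$num / pmax(tm$den, hp$eps)
}

# Draws n values uniformly on (0, width]; used for perturbations so every
# entry becomes strictly positive.
runif_pos <- function(n, width) {
  width * (1 - stats::runif(n))
}

#' Initialize memberships from a seed clustering
#'
#' Converts a seed clustering (e.g. the output of a Markov-process
#' clustering of the protein network, or any catalog read from disk) into a
#' binary indicator matrix with one column per seed cluster plus one
#' singleton column per unclustered protein, so `K = K_hat + N1 - N_hat`.
#' A small i.i.d. positive perturbation on `(0, perturb]` is then added to
#' every entry to break ties, and the relevance variances are set by
#' [update_lambda()].
#'
#' @param clusters a [complex_catalog] of seed groups (may overlap).
#' @param node_ids character vector: the full ordered protein universe.
#' @param hp an [mnc_hyperparams] object; `hp$seed`, if non-`NULL`, seeds
#'   the perturbation.
#' @return A [membership_state].
#' @export
initialize_from_clustering <- function(clusters, node_ids,
                                       hp = mnc_hyperparams()) {
  node_ids <- as.character(node_ids)
  unknown <- setdiff(unique(unlist(clusters)), node_ids)
  if (length(unknown))
    stop("seed clusters reference unknown node ids: ",
         paste(unknown, collapse = ", "))
  n1 <- length(node_ids)
  H <- matrix(0, n1, length(clusters),
              dimnames = list(node_ids, names(clusters)))
  for (k in seq_along(clusters))
    H[clusters[[k]], k] <- 1
  unclustered <- node_ids[rowSums(H) == 0]
  if (length(unclustered)) {
    Hs <- matrix(0, n1, length(unclustered),
                 dimnames = list(node_ids, paste0("S_", unclustered)))
    Hs[cbind(unclustered, colnames(Hs))] <- 1
    H <- cbind(H, Hs)
  }
  if (!is.null(hp$seed)) set.seed(hp$seed)
  H <- H + matrix(runif_pos(length(H), hp$perturb), nrow(H), ncol(H))
  membership_state(H, update_lambda(H, hp))
}

#' Initialize memberships randomly
#'
#' All entries are drawn i.i.d. uniformly on `(0, perturb]`. With a large
#' `K` the relevance prior prunes superfluous columns during fitting, so `K`
#' acts as an upper bound on the number of recoverable complexes.
#'
#' @param n1 number of proteins.
#' @param K number of cluster columns.
#' @param hp an [mnc_hyperparams] object; `hp$seed`, if non-`NULL`, makes
#'   the draw reproducible.
#' @return A [membership_state].
#' @export
initialize_random <- function(n1, K, hp = mnc_hyperparams()) {
  stopifnot(n1 >= 1, K >= 1)
  if (!is.null(hp$seed)) set.seed(hp$seed)
  H <- matrix(runif_pos(n1 * K, hp$perturb), n1, K)
  membership_state(H, update_lambda(H, hp))
}

#' Fit the multi-network clustering model
#'
#' Alternates the closed-form relevance update and the multiplicative
#' membership update, recording the objective after every sweep, until the
#' relative objective change drops below `hp$tol` or `hp$max_iter` sweeps
#' have run. Columns whose largest entry has fallen below 1e-8 are frozen
#' (left untouched) to keep column indices stable; they are removed later by
#' thresholding.
#'
#' @param A1 protein-layer [interaction_network].
#' @param A2 domain-layer [interaction_network], or `NULL` for a
#'   single-network fit.
#' @param F_map [association_map]; required when `A2` is given.
#' @param init starting [membership_state] (see
#'   [initialize_from_clustering()], [initialize_random()]).
#' @param hp an [mnc_hyperparams] object.
#' @return An object of class `mnc_fit`: `state` (final memberships),
#'   `objective_trace`, `n_iter`, `converged`, `seed_used`.
#' @examples
#' sim <- sample_instance(planted_design(n_proteins = 30, n_domains = 12,
#'                                       n_clusters = 3, seed = 1))
#' hp <- mnc_hyperparams(seed = 1)
#' init <- initialize_from_clustering(sim$reference, sim$ppi$node_ids, hp)
#' fit <- mnc_fit(sim$ppi, sim$ddi, sim$associations, init, hp)
#' @export
mnc_fit <- function(A1, A2 = NULL, F_map = NULL, init, hp = mnc_hyperparams()) {
  if (!is.null(A2) && is.null(F_map))
    stop("F_map is required when a second network layer is supplied")
  H <- init$H
  lambda <- init$lambda
  obj <- mnc_objective(A1, A2, F_map, membership_state(H, lambda), hp)
  check_finite_objective(A1, A2, F_map, H, lambda, hp, obj)
  trace <- obj
  converged <- FALSE
  iter <- 0L
  for (t in seq_len(hp$max_iter)) {
    iter <- t
    lambda <- update_lambda(H, hp)
    frozen <- apply(H, 2, max) < 1e-8
    H_new <- update_H(A1, A2, F_map, membership_state(H, lambda), hp)
    if (any(frozen)) H_new[, frozen] <- H[, frozen]
    H <- H_new
    obj_new <- mnc_objective(A1, A2, F_map, membership_state(H, lambda), hp)
    check_finite_objective(A1, A2, F_map, H, lambda, hp, obj_new)
    trace <- c(trace, obj_new)
    if (abs(obj_new - obj) / max(abs(obj), 1e-12) < hp$tol) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  structure(list(state = membership_state(H, lambda),
                 objective_trace = trace, n_iter = iter,
                 converged = converged, seed_used = hp$seed),
            class = "mnc_fit")
}

# Abort with a diagnostic naming the offending term if the objective is
# non-finite.
check_finite_objective <- function(A1, A2, F_map, H, lambda, hp, obj) {
  if (is.finite(obj)) return(invisible(obj))
  parts <- c(ppi_loglik = -network_log_likelihood(A1, H, hp$eps),
             prior = prior_penalty(H, lambda, hp$a, resolve_b(hp, nrow(H))))
  if (!is.null(A2)) {
    Fm <- if (inherits(F_map, "association_map")) F_map$matrix else
      as.matrix(F_map)
    parts["ddi_loglik"] <- -network_log_likelihood(A2, Fm %*% H, hp$eps)
  }
  bad <- names(parts)[!is.finite(parts)]
  stop("objective became non-finite; offending term(s): ",
       paste(bad, collapse = ", "))
}

#' @export
print.mnc_fit <- function(x, ...) {
  cat(sprintf(paste0("<mnc_fit> %d iterations, %s (final objective %.6g, ",
                     "K = %d)\n"),
              x$n_iter, if (x$converged) "converged" else "not converged",
              x$objective_trace[length(x$objective_trace)], x$state$K))
  invisible(x)
}

#' Built-in Markov-process clustering of a network
#'
#' A lightweight expansion/inflation flow clustering usable to seed
#' [initialize_from_clustering()] when no external clustering is supplied.
#' Self-loops are added, the adjacency is column-normalized, and the process
#' alternates expansion (matrix squaring) with entrywise inflation
#' (power 2 and renormalization) until the matrix stabilizes or `max_iter`
#' rounds have run. Entries below `threshold` are pruned each round; the
#' clusters are the connected components of the support of the limit matrix.
#'
#' @param net an [interaction_network].
#' @param inflation inflation exponent (default 2).
#' @param max_iter maximum expansion/inflation rounds (default 100).
#' @param threshold prune-and-support threshold (default 1e-6).
#' @return A [complex_catalog] covering every node (singletons included).
#' @export
markov_cluster <- function(net, inflation = 2, max_iter = 100L,
                           threshold = 1e-6) {
  A <- if (inherits(net, "interaction_network")) net$adjacency else
    as.matrix(net)
  ids <- if (inherits(net, "interaction_network")) net$node_ids else
    paste0("n", seq_len(nrow(A)))
  n <- nrow(A)
  M <- A + diag(n)
  M <- sweep(M, 2, colSums(M), "/")
  for (t in seq_len(max_iter)) {
    M_new <- M %*% M
    M_new <- M_new^inflation
    M_new[M_new < threshold] <- 0
    cs <- colSums(M_new)
    cs[cs == 0] <- 1
    M_new <- sweep(M_new, 2, cs, "/")
    if (max(abs(M_new - M)) < 1e-9) {
      M <- M_new
      break
    }
    M <- M_new
  }
  support <- (M > threshold) | t(M > threshold)
  comp <- connected_components(support)
  complex_catalog(lapply(split(ids, comp), identity))
}

# Connected components of a logical adjacency matrix (BFS).
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}
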