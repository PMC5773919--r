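# Generative model: Bernoulli exponential-link likelihood shared across the
# protein and domain layers, half-normal/inverse-gamma (ARD) priors on the
# membership matrix. All likelihood sums run over ordered pairs i != j, so an
# undirected edge contributes twice; self-pairs carry no information (zero
# diagonal) and are excluded.

#' Co-cluster affinity matrix
#'
#' The model's edge probability: two nodes with membership rows `h_i`, `h_j`
#' interact with probability `W_ij = 1 - exp(-sum_k h_ik h_jk)`. Sharing mass
#' in any cluster pushes the probability toward 1; orthogonal memberships
#' give probability 0.
#'
#' @param H nonnegative numeric matrix (nodes x clusters).
#' @return Symmetric matrix with entries in `[0, 1)`.
#' @examples
#' co_cluster_affinity(rbind(c(1, 0), c(1, 0), c(0, 1)))
#' @export
co_cluster_affinity <- function(H) {
  H <- as.matrix(H)
  if (any(!is.finite(H)) || any(H < 0))
    stop("H must be finite and nonnegative")
  -expm1(-tcrossprod(H))
}

# log(1 - exp(-s)) with s floored at eps so zero-affinity edges stay finite.
log1mexp_neg <- function(s, eps) {
  log(-expm1(-pmax(s, eps)))
}

#' Bernoulli log-likelihood of one network layer
#'
#' Evaluates `sum_{i != j} [A_ij log(1 - exp(-S_ij)) - (1 - A_ij) S_ij]`
#' with `S = H_layer %*% t(H_layer)`, the log-probability of observing the
#' adjacency under the co-cluster affinity model. Ordered pairs are summed,
#' so each undirected edge is counted twice; the diagonal is excluded.
#'
#' For the domain layer pass `H_layer = F %*% H`.
#'
#' @param A an [interaction_network] or a binary symmetric matrix.
#' @param H_layer nonnegative membership matrix with as many rows as `A` has
#'   nodes.
#' @param eps floor applied to `S` inside the log (default 1e-10).
#' @return A single numeric log-likelihood (<= 0).
#' @export
network_log_likelihood <- function(A, H_layer, eps = 1e-10) {
  A <- if (inherits(A, "interaction_network")) A$adjacency else as.matrix(A)
  H_layer <- as.matrix(H_layer)
  if (nrow(A) != nrow(H_layer))
    stop("H_layer must have one row per node of A (got ",
         nrow(H_layer), " rows for ", nrow(A), " nodes)")
  S <- tcrossprod(H_layer)
  M <- (1 - A) * (-S)
  edge <- A > 0
  M[edge] <- A[edge] * log1mexp_neg(S[edge], eps)
  diag(M) <- 0
  sum(M)
}

# Prior terms of the negative log joint that depend on H and lambda:
#   sum_ik H_ik^2 / (2 lambda_k) + (N1/2) sum_k log lambda_k
#   + sum_k b / lambda_k + (a + 1) sum_k log lambda_k
prior_penalty <- function(H, lambda, a, b) {
  n1 <- nrow(H)
  sum(sweep(H^2, 2, 2 * lambda, "/")) +
    (n1 / 2) * sum(log(lambda)) +
    sum(b / lambda) +
    (a + 1) * sum(log(lambda))
}

#' Negative log joint objective of the multi-network model
#'
#' The quantity minimized during fitting: the negative Bernoulli
#' log-likelihood of the protein network given `H`, plus that of the domain
#' network given `F %*% H`, plus the half-normal membership penalty
#' `sum H_ik^2 / (2 lambda_k)` and the inverse-gamma relevance penalty
#' `(N1/2 + a + 1) sum log lambda_k + sum b / lambda_k`.
#'
#' @param A1 protein-layer [interaction_network] (or adjacency matrix).
#' @param A2 domain-layer [interaction_network], or `NULL` to fit the
#'   protein network alone (single-layer ablation).
#' @param F_map [association_map] (or matrix) coupling the layers; required
#'   when `A2` is given.
#' @param state a [membership_state].
#' @param hp an [mnc_hyperparams] object.
#' @return A single numeric objective value (lower is better).
#' @export
mnc_objective <- function(A1, A2, F_map, state, hp = mnc_hyperparams()) {
  H <- state$H
  lambda <- state$lambda
  if (any(lambda <= 0)) stop("all lambda_k must be positive")
  n1 <- nrow(H)
  b <- resolve_b(hp, n1)
  obj <- -network_log_likelihood(A1, H, hp$eps) +
    prior_penalty(H, lambda, hp$a, b)
  if (!is.null(A2)) {
    Fm <- if (inherits(F_map, "association_map")) F_map$matrix else
      as.matrix(F_map)
    if (ncol(Fm) != n1)
      stop("association map has ", ncol(Fm), " protein columns but H has ",
           n1, " rows")
    obj <- obj - network_log_likelihood(A2, Fm %*% H, hp$eps)
  }
  obj
}
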