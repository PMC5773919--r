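# Independent naive-loop oracles. These deliberately use scalar loops and
# textbook formulas, sharing no code with the package implementation.

# Negative log joint, scalar loops over ordered pairs i != j.
naive_objective <- function(A1, A2, Fm, H, lambda, a, b, eps = 1e-10) {
  loglik <- function(A, M) {
    n <- nrow(A)
    total <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      s <- sum(M[i, ] * M[j, ])
      total <- total +
        if (A[i, j] == 1) log(-expm1(-max(s, eps))) else -s
    }
    total
  }
  obj <- -loglik(A1, H)
  if (!is.null(A2)) obj <- obj - loglik(A2, Fm %*% H)
  n1 <- nrow(H)
  for (k in seq_along(lambda)) {
    for (i in seq_len(n1)) obj <- obj + H[i, k]^2 / (2 * lambda[k])
    obj <- obj + (n1 / 2) * log(lambda[k]) + b / lambda[k] +
      (a + 1) * log(lambda[k])
  }
  obj
}

# Multiplicative membership update, quadruple scalar loops. Sums over node
# pairs exclude self-pairs (j = i, y = x), matching the objective.
naive_update_H <- function(A1, A2, Fm, H, lambda, eps = 1e-10) {
  n1 <- nrow(H)
  K <- ncol(H)
  S1 <- H %*% t(H)
  G <- if (is.null(A2)) NULL else Fm %*% H
  S2 <- if (is.null(A2)) NULL else G %*% t(G)
  H_new <- H
  for (i in seq_len(n1)) for (k in seq_len(K)) {
    num <- 0
    den <- 0
    for (j in seq_len(n1)) {
      if (j == i) next
      num <- num + A1[i, j] * H[j, k] / (-expm1(-max(S1[i, j], eps)))
      den <- den + H[j, k]
    }
    if (!is.null(A2)) {
      n2 <- nrow(A2)
      for (x in seq_len(n2)) for (y in seq_len(n2)) {
        if (y == x) next
        inner <- sum(H[, k] * Fm[y, ])
        num <- num +
          A2[x, y] * Fm[x, i] * inner / (-expm1(-max(S2[x, y], eps)))
        den <- den + Fm[x, i] * inner
      }
    }
    den <- den + H[i, k] / (2 * lambda[k])
    H_new[i, k] <- H[i, k] / 2 + (H[i, k] / 2) * num / max(den, eps)
  }
  H_new
}

# Sn / PPV / Acc by direct double loops over catalog pairs.
naive_accuracy <- function(benchmark, predicted) {
  sn_num <- 0
  for (b in benchmark) {
    best <- 0
    for (q in predicted) best <- max(best, length(intersect(b, q)))
    sn_num <- sn_num + best
  }
  ppv_num <- 0
  ppv_den <- 0
  for (q in predicted) {
    best <- 0
    covered <- character()
    for (b in benchmark) {
      ov <- intersect(b, q)
      best <- max(best, length(ov))
      covered <- union(covered, ov)
    }
    ppv_num <- ppv_num + best
    ppv_den <- ppv_den + length(covered)
  }
  sn <- sn_num / sum(lengths(benchmark))
  ppv <- ppv_num / ppv_den
  list(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

# Exact hypergeometric upper tail P(X >= z) by summing the mass function
# with choose().
naive_hyper_tail <- function(N, C, S, z) {
  if (z == 0) return(1)
  l <- z:min(C, S)
  sum(choose(S, l) * choose(N - S, C - l)) / choose(N, C)
}

# Random small test instance: Bernoulli networks, association map,
# positive memberships.
random_instance <- function(n1, n2, K, seed) {
  set.seed(seed)
  sym01 <- function(n, p) {
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
    A + t(A)
  }
  list(A1 = sym01(n1, 0.4),
       A2 = sym01(n2, 0.4),
       Fm = matrix(rbinom(n2 * n1, 1, 0.3), n2, n1),
       H = matrix(runif(n1 * K, 0, 1.5), n1, K),
       lambda = runif(K, 0.2, 2))
}

# Small fixture used by the fit-behaviour tests: a planted instance plus a
# perturbed-truth starting point under one seed.
fit_fixture <- function(seed, n_proteins = 24, n_domains = 10,
                        n_clusters = 3, tol = 1e-3, max_iter = 500) {
  sim <- sample_instance(planted_design(
    n_proteins = n_proteins, n_domains = n_domains, n_clusters = n_clusters,
    seed = seed))
  hp <- mnc_hyperparams(seed = seed, tol = tol, max_iter = max_iter)
  init <- initialize_from_clustering(sim$reference, sim$ppi$node_ids, hp)
  list(sim = sim, hp = hp, init = init)
}
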