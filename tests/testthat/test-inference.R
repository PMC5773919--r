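# Alternating optimization: relevance update, multiplicative membership
# update, initialization, convergence behaviour.

test_that("update_lambda matches hand arithmetic", {
  hp1 <- mnc_hyperparams(a = 2, b = 1)
  expect_equal(update_lambda(matrix(0, 10, 1), hp1), 2 / 16) # = 0.125
  hp2 <- mnc_hyperparams(a = 2, b = 0.5)
  expect_equal(update_lambda(matrix(1, 3, 1), hp2), 4 / 9)
})

test_that("update_lambda is the exact minimizer of the lambda terms", {
  for (seed in 1:50) {
    set.seed(seed)
    n1 <- sample(3:12, 1)
    H <- matrix(runif(n1 * 2, 0, 2), n1, 2)
    a <- runif(1, 0.5, 4); b <- runif(1, 0.1, 5)
    hp <- mnc_hyperparams(a = a, b = b)
    lam <- update_lambda(H, hp)
    for (k in 1:2) {
      f <- function(l) sum(H[, k]^2) / (2 * l) +
        (n1 / 2 + a + 1) * log(l) + b / l
      opt <- stats::optimize(f, c(1e-6, 50), tol = 1e-10)$minimum
      expect_equal(lam[k], opt, tolerance = 1e-6)
    }
  }
})

test_that("update_H fixes zeros and shrinks isolated nodes", {
  hp <- mnc_hyperparams()
  # single node in each layer, no possible edges: pure halving
  A1 <- matrix(0, 1, 1); A2 <- matrix(0, 1, 1); Fm <- matrix(1, 1, 1)
  st <- membership_state(matrix(0.8, 1, 1), 0.5)
  expect_equal(update_H(A1, A2, Fm, st, hp), matrix(0.4, 1, 1))
  # zero entries are absorbing
  inst <- random_instance(5, 3, 2, seed = 3)
  inst$H[2, 1] <- 0
  st <- membership_state(inst$H, inst$lambda)
  expect_equal(update_H(inst$A1, inst$A2, inst$Fm, st, hp)[2, 1], 0)
})

test_that("update_H matches the naive quadruple-loop oracle", {
  hp <- mnc_hyperparams()
  for (seed in 1:20) {
    inst <- random_instance(8, 5, 2, seed = seed)
    st <- membership_state(inst$H, inst$lambda)
    expect_equal(update_H(inst$A1, inst$A2, inst$Fm, st, hp),
                 naive_update_H(inst$A1, inst$A2, inst$Fm, inst$H,
                                inst$lambda),
                 tolerance = 1e-9)
    # single-layer variant
    expect_equal(update_H(inst$A1, NULL, NULL, st, hp),
                 naive_update_H(inst$A1, NULL, NULL, inst$H, inst$lambda),
                 tolerance = 1e-9)
  }
})

test_that("indicator initialization builds the expected binary pattern", {
  hp <- mnc_hyperparams(seed = 42)
  cat <- complex_catalog(list(c1 = c("n1", "n2"), c2 = "n3"))
  st <- initialize_from_clustering(cat, paste0("n", 1:4), hp)
  expect_equal(ncol(st$H), 3) # K = K_hat + N1 - N_hat = 2 + 4 - 3
  expect_equal(floor(st$H),
               rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               ignore_attr = TRUE)
  # perturbation: everything strictly positive, formerly-1 in (1, 1.01]
  expect_true(all(st$H > 0))
  ones <- st$H[floor(st$H) == 1]
  expect_true(all(ones > 1 & ones <= 1 + hp$perturb))
  expect_equal(st$lambda, unname(update_lambda(st$H, hp)))
})

test_that("all-unclustered initialization gives an identity pattern", {
  st <- initialize_from_clustering(complex_catalog(), paste0("n", 1:5),
                                   mnc_hyperparams(seed = 1))
  expect_equal(floor(st$H), diag(5), ignore_attr = TRUE)
})

test_that("unknown seed-cluster labels are reported", {
  expect_error(
    initialize_from_clustering(complex_catalog(list(c("n1", "zz"))),
                               c("n1", "n2"), mnc_hyperparams()),
    "zz")
})

test_that("random initialization is seed-reproducible and in range", {
  hp <- mnc_hyperparams(seed = 7)
  a <- initialize_random(20, 4, hp)
  b <- initialize_random(20, 4, hp)
  expect_identical(a$H, b$H)
  expect_true(all(a$H > 0 & a$H <= hp$perturb))
  c <- initialize_random(20, 4, mnc_hyperparams(seed = 8))
  expect_false(identical(a$H, c$H))
})

test_that("a stationary start converges immediately", {
  A1 <- interaction_network(matrix(0, 4, 4))
  hp <- mnc_hyperparams()
  init <- membership_state(matrix(0, 4, 2), update_lambda(matrix(0, 4, 2), hp))
  expect_warning(fit <- mnc_fit(A1, init = init, hp = hp), "collapsed")
  expect_true(fit$converged)
  expect_lte(fit$n_iter, 2)
})

test_that("the objective never ends above its starting value", {
  for (seed in 1:8) {
    fx <- fit_fixture(seed)
    fit <- mnc_fit(fx$sim$ppi, fx$sim$ddi, fx$sim$associations,
                   fx$init, fx$hp)
    tr <- fit$objective_trace
    expect_lte(tr[length(tr)], tr[1])
    expect_true(all(fit$state$H >= 0))
  }
})

test_that("converged fits are approximately stationary", {
  for (seed in 1:5) {
    fx <- fit_fixture(seed, tol = 1e-12, max_iter = 20000)
    fit <- mnc_fit(fx$sim$ppi, fx$sim$ddi, fx$sim$associations,
                   fx$init, fx$hp)
    expect_true(fit$converged)
    ratio <- mnc_multiplier_ratio(fx$sim$ppi, fx$sim$ddi,
                                  fx$sim$associations, fit$state, fx$hp)
    active <- fit$state$H > 1e-6
    expect_true(all(abs(ratio[active] - 1) <= 1e-2))
  }
})

test_that("permuting init columns permutes the fitted columns identically", {
  fx <- fit_fixture(3, n_proteins = 18, n_domains = 8)
  fit <- mnc_fit(fx$sim$ppi, fx$sim$ddi, fx$sim$associations, fx$init, fx$hp)
  p <- c(3, 1, 2)
  init_p <- membership_state(fx$init$H[, p], fx$init$lambda[p])
  fit_p <- mnc_fit(fx$sim$ppi, fx$sim$ddi, fx$sim$associations,
                   init_p, fx$hp)
  expect_equal(fit_p$state$H, fit$state$H[, p], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fit_p$state$lambda, fit$state$lambda[p], tolerance = 1e-10)
})

test_that("built-in Markov clustering splits disconnected blocks", {
  # two 4-cliques joined by nothing -> two clusters
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  net <- interaction_network(A, paste0("n", 1:8))
  cl <- markov_cluster(net)
  sets <- lapply(cl, sort)
  expect_true(any(vapply(sets, identical, TRUE, paste0("n", 1:4))))
  expect_true(any(vapply(sets, identical, TRUE, paste0("n", 5:8))))
  expect_setequal(unlist(cl), paste0("n", 1:8))
})
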