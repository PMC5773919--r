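# Complex-matching metrics and hypergeometric enrichment.

test_that("Sn/PPV/Acc match the worked one-complex example", {
  b <- complex_catalog(list(c("p1", "p2", "p3")))
  q <- complex_catalog(list(c("p1", "p2", "p4")))
  m <- accuracy_metrics(b, q)
  expect_equal(m$sn, 2 / 3)
  expect_equal(m$ppv, 1)
  expect_equal(m$acc, sqrt(2 / 3))
  # identity and disjoint cases
  expect_equal(accuracy_metrics(b, b)$acc, 1)
  disj <- accuracy_metrics(b, complex_catalog(list(c("x", "y"))))
  expect_equal(disj$sn, 0)
  expect_equal(disj$acc, 0)
  expect_warning(accuracy_metrics(b, complex_catalog()), "empty")
})

test_that("accuracy metrics agree with the brute-force oracle", {
  for (seed in 1:30) {
    set.seed(seed)
    prot <- paste0("p", 1:20)
    rand_cat <- function() complex_catalog(lapply(
      seq_len(sample(2:8, 1)),
      function(i) sample(prot, sample(2:6, 1))))
    b <- rand_cat(); q <- rand_cat()
    got <- accuracy_metrics(b, q)
    want <- naive_accuracy(b, q)
    expect_equal(got$sn, want$sn, tolerance = 1e-12)
    expect_equal(got$ppv, want$ppv, tolerance = 1e-12)
    expect_equal(got$acc, want$acc, tolerance = 1e-12)
  }
})

test_that("overlap score matches its definition", {
  expect_equal(overlap_score(letters[1:3], letters[1:3]), 1)
  expect_equal(overlap_score(c("1", "2", "3", "4"), c("3", "4", "5", "6")),
               0.25)
  expect_equal(overlap_score("a", "b"), 0)
  expect_error(overlap_score(character(), "a"), "empty")
})

test_that("FRAC counts benchmark complexes with a match at omega", {
  b <- complex_catalog(list(c("1", "2", "3", "4")))
  expect_equal(frac_matched(b, b, 0.25), 1)
  # boundary: OS exactly omega counts as matched
  q <- complex_catalog(list(c("3", "4", "5", "6")))
  expect_equal(frac_matched(b, q, 0.25), 1)
  expect_equal(frac_matched(b, complex_catalog(), 0.25), 0)
  expect_error(frac_matched(complex_catalog(), b), "empty")
})

test_that("precision/recall/F match the worked example", {
  b <- complex_catalog(list(c("1", "2", "3")))
  q <- complex_catalog(list(c("1", "2", "3"), c("7", "8", "9")))
  r <- prf(b, q, 0.25)
  expect_equal(r$tp, 1L); expect_equal(r$fp, 1L); expect_equal(r$fn, 0L)
  expect_equal(r$precision, 0.5)
  expect_equal(r$recall, 1)
  expect_equal(r$f_measure, 2 / 3)
  perfect <- prf(b, b, 0.25)
  expect_equal(perfect$f_measure, 1)
  nomatch <- suppressWarnings(
    prf(b, complex_catalog(list(c("x", "y", "z"))), 0.25))
  expect_equal(c(nomatch$precision, nomatch$recall, nomatch$f_measure),
               c(0, 0, 0))
})

test_that("FRAC, TP and recall are monotone nonincreasing in omega", {
  set.seed(9)
  prot <- paste0("p", 1:25)
  b <- complex_catalog(lapply(1:6, function(i) sample(prot, sample(3:7, 1))))
  q <- complex_catalog(lapply(1:6, function(i) sample(prot, sample(3:7, 1))))
  omegas <- c(0.1, 0.25, 0.5, 0.75, 1)
  fr <- vapply(omegas, function(w) frac_matched(b, q, w), 0)
  tp <- vapply(omegas, function(w) suppressWarnings(prf(b, q, w)$tp), 0L)
  rc <- vapply(omegas, function(w) suppressWarnings(prf(b, q, w)$recall), 0)
  expect_true(all(diff(fr) <= 0))
  expect_true(all(diff(tp) <= 0))
  expect_true(all(diff(rc) <= 1e-12))
})

test_that("metrics ignore complex names and catalog order", {
  set.seed(12)
  prot <- paste0("p", 1:15)
  b <- complex_catalog(lapply(1:4, function(i) sample(prot, 4)))
  q <- complex_catalog(lapply(1:4, function(i) sample(prot, 4)))
  q2 <- complex_catalog(stats::setNames(unclass(q)[c(3, 1, 4, 2)],
                                        paste0("z", 1:4)))
  expect_equal(accuracy_metrics(b, q)$acc, accuracy_metrics(b, q2)$acc)
  expect_equal(frac_matched(b, q), frac_matched(b, q2))
  expect_equal(prf(b, q)$tp, prf(b, q2)$tp)
})

test_that("enrichment P-value matches exact enumeration", {
  expect_equal(enrichment_pvalue(10, 3, 5, 0), 1)
  expect_equal(enrichment_pvalue(10, 3, 5, 3), 10 / 120)
  set.seed(4)
  for (rep in 1:40) {
    N <- sample(10:60, 1)
    C <- sample(1:min(15, N), 1)
    S <- sample(1:N, 1)
    z <- sample(0:min(C, S), 1)
    expect_equal(enrichment_pvalue(N, C, S, z),
                 naive_hyper_tail(N, C, S, z), tolerance = 1e-12)
  }
  expect_error(enrichment_pvalue(10, 3, 5, 4), "inconsistent")
})

test_that("enrichment P-value is nonincreasing in the overlap z", {
  p <- vapply(0:5, function(z) enrichment_pvalue(30, 6, 5, z), 0)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("catalog enrichment reports per-complex minima and flags", {
  ann <- list(t1 = paste0("p", 1:5), t2 = paste0("p", 6:10))
  cat <- complex_catalog(list(inT1 = paste0("p", 1:5),
                              none = paste0("q", 1:3)))
  res <- suppressWarnings(
    enrich_catalog(cat, ann, background = 20, alpha = 1e-2))
  expect_equal(res$p_value[res$complex == "inT1"],
               enrichment_pvalue(20, 5, 5, 5))
  expect_true(res$significant[res$complex == "inT1"])
  expect_equal(res$p_value[res$complex == "none"], 1)
  expect_false(res$significant[res$complex == "none"])
  # Bonferroni factor multiplies by the number of terms
  resb <- suppressWarnings(
    enrich_catalog(cat, ann, background = 20, bonferroni = TRUE))
  expect_equal(resb$p_adjusted, pmin(resb$p_value * 2, 1))
})

test_that("planted annotations make planted complexes enrich", {
  sim <- sample_instance(planted_design(n_proteins = 40, n_domains = 15,
                                        n_clusters = 4, seed = 11))
  res <- enrich_catalog(sim$reference, sim$annotations,
                        background = 40, alpha = 1e-2)
  expect_true(all(res$significant))
})
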