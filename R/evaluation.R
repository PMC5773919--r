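# Complex-matching evaluation: clustering-wise Sn/PPV/Acc, overlap-score
# matching (FRAC, precision/recall/F), and hypergeometric enrichment.

# Overlap-count matrix T[i, j] = |benchmark_i intersect predicted_j|.
overlap_counts <- function(benchmark, predicted) {
  vapply(predicted, function(q)
    vapply(benchmark, function(b) length(intersect(b, q)), 0L),
    integer(length(benchmark)))
}

#' Clustering-wise sensitivity, positive predictive value and accuracy
#'
#' With `T[i, j]` the number of proteins shared by benchmark complex `b_i`
#' and predicted complex `q_j`:
#' `Sn = sum_i max_j T[i, j] / sum_i |b_i|` (how much of each benchmark
#' complex its best-covering prediction recovers),
#' `PPV = sum_j max_i T[i, j] / sum_j |q_j ∩ U|` where `U` is the union of
#' all benchmark members (how concentrated each prediction is on a single
#' benchmark complex), and `Acc = sqrt(Sn * PPV)`.
#'
#' @param benchmark,predicted [complex_catalog] objects.
#' @return List with `sn`, `ppv`, `acc`.
#' @examples
#' accuracy_metrics(complex_catalog(list(c("p1", "p2", "p3"))),
#'                  complex_catalog(list(c("p1", "p2", "p4"))))
#' @export
accuracy_metrics <- function(benchmark, predicted) {
  if (length(benchmark) == 0 || length(predicted) == 0) {
    warning("empty catalog: Sn/PPV/Acc reported as 0")
    return(list(sn = 0, ppv = 0, acc = 0))
  }
  Tm <- overlap_counts(benchmark, predicted)
  dim(Tm) <- c(length(benchmark), length(predicted))
  sn <- sum(apply(Tm, 1, max)) / sum(lengths(benchmark))
  universe <- unique(unlist(benchmark))
  denom <- sum(vapply(predicted,
                      function(q) length(intersect(q, universe)), 0L))
  ppv <- if (denom > 0) sum(apply(Tm, 2, max)) / denom else 0
  list(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

#' Overlap score between two complexes
#'
#' `OS(b, q) = |b ∩ q|^2 / (|b| |q|)`: 1 for identical sets, 0 for disjoint
#' ones, and the squared intersection penalizes both missed and spurious
#' members symmetrically.
#'
#' @param b,q non-empty character vectors of member labels.
#' @return A number in `[0, 1]`.
#' @export
overlap_score <- function(b, q) {
  b <- unique(as.character(b))
  q <- unique(as.character(q))
  if (length(b) == 0 || length(q) == 0)
    stop("overlap_score is undefined for empty sets")
  length(intersect(b, q))^2 / (length(b) * length(q))
}

# OS matrix between two catalogs (benchmark rows, predicted columns).
os_matrix <- function(benchmark, predicted) {
  m <- vapply(predicted, function(q)
    vapply(benchmark, function(b) overlap_score(b, q), 0),
    numeric(length(benchmark)))
  dim(m) <- c(length(benchmark), length(predicted))
  dimnames(m) <- list(names(benchmark), names(predicted))
  m
}

#' Fraction of benchmark complexes matched
#'
#' The share of benchmark complexes for which at least one predicted
#' complex reaches overlap score `>= omega`.
#'
#' @param benchmark,predicted [complex_catalog] objects; `benchmark` must be
#'   non-empty.
#' @param omega overlap-score match threshold (default 0.25).
#' @return A number in `[0, 1]`.
#' @export
frac_matched <- function(benchmark, predicted, omega = 0.25) {
  if (length(benchmark) == 0) stop("benchmark catalog is empty")
  if (length(predicted) == 0) return(0)
  os <- os_matrix(benchmark, predicted)
  mean(apply(os, 1, max) >= omega)
}

#' Precision, recall and F-measure of complex matching
#'
#' `TP` counts predicted complexes matched (OS `>= omega`) by at least one
#' benchmark complex, `FN` counts benchmark complexes matched by no
#' prediction, and `FP` is the number of predictions minus `TP`; then
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)` and F is their
#' harmonic mean. Note that because reference complex sets are incomplete,
#' unmatched predictions are not necessarily wrong — they may be novel
#' complexes — so precision and F understate performance on real data.
#'
#' @inheritParams frac_matched
#' @return List with `precision`, `recall`, `f_measure`, `tp`, `fp`, `fn`,
#'   and `matched_pairs` (data frame of benchmark/predicted/OS for every
#'   matching pair).
#' @export
prf <- function(benchmark, predicted, omega = 0.25) {
  if (length(benchmark) == 0) stop("benchmark catalog is empty")
  empty_pairs <- data.frame(benchmark = character(), predicted = character(),
                            os = numeric(), stringsAsFactors = FALSE)
  if (length(predicted) == 0) {
    warning("no predicted complexes: precision/recall/F reported as 0")
    return(list(precision = 0, recall = 0, f_measure = 0,
                tp = 0L, fp = 0L, fn = length(benchmark),
                matched_pairs = empty_pairs))
  }
  os <- os_matrix(benchmark, predicted)
  hit <- os >= omega
  tp <- sum(apply(hit, 2, any))
  fn <- sum(!apply(hit, 1, any))
  fp <- length(predicted) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  if (tp + fn == 0 || precision + recall == 0)
    warning("degenerate matching: zero denominators reported as 0")
  idx <- which(hit, arr.ind = TRUE)
  pairs <- if (nrow(idx)) data.frame(
    benchmark = names(benchmark)[idx[, 1]],
    predicted = names(predicted)[idx[, 2]],
    os = os[idx], stringsAsFactors = FALSE) else empty_pairs
  list(precision = precision, recall = recall, f_measure = f,
       tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
       matched_pairs = pairs)
}

#' Full metric report for a predicted catalog
#'
#' Convenience wrapper combining [accuracy_metrics()], [frac_matched()] and
#' [prf()] into one report.
#'
#' @inheritParams frac_matched
#' @return List of class `metric_report`.
#' @export
evaluate_catalogs <- function(benchmark, predicted, omega = 0.25) {
  acc <- accuracy_metrics(benchmark, predicted)
  p <- prf(benchmark, predicted, omega)
  structure(c(acc,
              list(frac = frac_matched(benchmark, predicted, omega),
                   omega = omega),
              p),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("Sn = %.4f  PPV = %.4f  Acc = %.4f\n",
                     "FRAC = %.4f (omega = %g)\n",
                     "precision = %.4f  recall = %.4f  F = %.4f ",
                     "(TP %d, FP %d, FN %d)\n"),
              x$sn, x$ppv, x$acc, x$frac, x$omega,
              x$precision, x$recall, x$f_measure, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Hypergeometric enrichment P-value
#'
#' The chance of observing `z` or more annotated proteins in a complex of
#' size `C` drawn from a background of `N` proteins of which `S` carry the
#' annotation: the upper tail `P(X >= z)` of the hypergeometric
#' distribution, i.e. `1 - sum_{l=0}^{z-1} choose(S, l) choose(N-S, C-l) /
#' choose(N, C)`. `z = 0` gives exactly 1.
#'
#' @param N background size.
#' @param C complex size.
#' @param S annotation (functional group) size.
#' @param z overlap between complex and annotation.
#' @return A probability in `[0, 1]`.
#' @examples
#' enrichment_pvalue(10, 3, 5, 3) # = choose(5,3)/choose(10,3) = 1/12
#' @export
enrichment_pvalue <- function(N, C, S, z) {
  if (any(c(N, C, S, z) < 0) || C > N || S > N || z > min(C, S))
    stop("inconsistent counts: need 0 <= z <= min(C, S) <= N")
  if (z == 0) return(1)
  p <- stats::phyper(z - 1, S, N - S, C, lower.tail = FALSE)
  min(max(p, 0), 1)
}

#' Functional enrichment of a predicted catalog
#'
#' Scores every predicted complex against every annotation term with the
#' hypergeometric upper-tail P-value and reports, per complex, the smallest
#' P-value, its term, and a significance flag at level `alpha`. A complex
#' with no annotated member gets P-value 1. Optionally a Bonferroni factor
#' equal to the number of terms tested is applied (off by default; the raw
#' minimum is always reported).
#'
#' @param predicted a [complex_catalog].
#' @param annotations named list: term id -> character vector of annotated
#'   proteins.
#' @param background background size `N`; defaults to the number of
#'   distinct proteins appearing in `predicted` and `annotations` combined.
#'   Conventionally set to the number of proteins in the analyzed network.
#' @param alpha significance threshold on the (possibly corrected) minimum
#'   P-value (default 1e-2).
#' @param bonferroni logical; apply a Bonferroni factor of `length(terms)`
#'   (default `FALSE`).
#' @param full logical; if `TRUE` also return the complete complex-by-term
#'   table.
#' @return Data frame with one row per complex: `complex`, `size`,
#'   `best_term`, `overlap`, `term_size`, `p_value`, `p_adjusted`,
#'   `significant`. With `full = TRUE`, a list with elements `summary` and
#'   `table`.
#' @export
enrich_catalog <- function(predicted, annotations, background = NULL,
                           alpha = 1e-2, bonferroni = FALSE, full = FALSE) {
  if (length(annotations) == 0) stop("annotation table is empty")
  if (length(predicted) == 0) {
    empty <- data.frame(complex = character(), size = integer(),
                        best_term = character(), term_size = integer(),
                        overlap = integer(), p_value = numeric(),
                        p_adjusted = numeric(), significant = logical(),
                        stringsAsFactors = FALSE)
    return(if (full) list(summary = empty, table = empty) else empty)
  }
  annotations <- lapply(annotations, function(p) unique(as.character(p)))
  annotated <- unique(unlist(annotations))
  if (is.null(background))
    background <- length(unique(c(annotated, unlist(predicted))))
  stray <- setdiff(unlist(predicted), annotated)
  if (length(stray))
    warning(length(stray),
            " predicted proteins carry no annotation and only count",
            " toward complex size")
  n_terms <- length(annotations)
  rows <- lapply(seq_along(predicted), function(j) {
    members <- predicted[[j]]
    C <- length(members)
    p_per_term <- vapply(seq_len(n_terms), function(t) {
      S <- length(annotations[[t]])
      z <- length(intersect(members, annotations[[t]]))
      enrichment_pvalue(background, C, S, z)
    }, 0)
    best <- which.min(p_per_term)
    data.frame(complex = names(predicted)[j], size = C,
               term = names(annotations), term_size = lengths(annotations),
               overlap = vapply(annotations, function(a)
                 length(intersect(members, a)), 0L),
               p_value = p_per_term,
               best = seq_len(n_terms) == best,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  table <- do.call(rbind, rows)
  summary <- table[table$best, , drop = FALSE]
  summary$best <- NULL
  names(summary)[names(summary) == "term"] <- "best_term"
  summary$p_adjusted <- if (bonferroni)
    pmin(summary$p_value * n_terms, 1) else summary$p_value
  summary$significant <- summary$p_adjusted < alpha
  rownames(summary) <- NULL
  if (full) list(summary = summary, table = table[names(table) != "best"])
  else summary
}
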