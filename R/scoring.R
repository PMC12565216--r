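#' Conventional ultrasound (CUS) score total and positivity
#'
#' The CUS score sums three visually rated components: parenchymal
#' echotexture grade (0-3, homogeneous to extensively coarse/heterogeneous),
#' liver echogenicity relative to the renal cortex (0 lower, 1 equal,
#' 2 higher), and ascites (0/1), so the total spans 0-6. A scan is screened
#' positive when the total is >= 1 — the only rule consistent with the
#' published confusion counts, where the true negatives are exactly the
#' CUS = 0 animals.
#'
#' @param parenchyma Ordinal 0-3.
#' @param relative_echogenicity Ordinal 0-2.
#' @param ascites 0 or 1.
#' @return `cus_total()`: integer total; `cus_positive()`: logical.
#' @export
cus_total <- function(parenchyma, relative_echogenicity, ascites) {
  check_ordinal(parenchyma, 3L, "parenchyma")
  check_ordinal(relative_echogenicity, 2L, "relative_echogenicity")
  check_ordinal(ascites, 1L, "ascites")
  as.integer(parenchyma + relative_echogenicity + ascites)
}

#' @rdname cus_total
#' @param total CUS total (0-6), e.g. from `cus_total()`.
#' @export
cus_positive <- function(total) {
  check_ordinal(total, 6L, "total")
  total >= 1L
}

check_ordinal <- function(x, max, name) {
  if (any(is.na(x)) || any(x < 0L) || any(x > max) || any(x != round(x))) {
    abort(sprintf("`%s` must be integers in 0..%d.", name, max))
  }
  invisible(x)
}

#' Steatosis severity score (SSS) total and class
#'
#' The histological SSS is the sum of three 0-3 semiquantitative grades:
#' macrovesicular steatosis, microvesicular steatosis, and hepatocyte
#' hypertrophy (total 0-9). Severity classes: none (0), mild (1-2),
#' moderate (3-4), severe (5-7). Totals of 8-9 are arithmetically possible
#' but outside the published class table; they are mapped to severe and
#' flagged via `attr(, "out_of_table")` rather than rejected.
#'
#' @param macro,micro,hypertrophy Ordinals 0-3.
#' @return `sss_total()`: integer total; `sss_class()`: ordered factor with
#'   levels none < mild < moderate < severe.
#' @export
sss_total <- function(macro, micro, hypertrophy) {
  check_ordinal(macro, 3L, "macro")
  check_ordinal(micro, 3L, "micro")
  check_ordinal(hypertrophy, 3L, "hypertrophy")
  as.integer(macro + micro + hypertrophy)
}

#' @rdname sss_total
#' @param total SSS total (0-9).
#' @export
sss_class <- function(total) {
  check_ordinal(total, 9L, "total")
  cls <- cut(total, breaks = c(-1, 0, 2, 4, 9),
             labels = c("none", "mild", "moderate", "severe"),
             ordered_result = TRUE)
  attr(cls, "out_of_table") <- total > 7L
  cls
}

#' Numeric steatosis grade (0-3) from the SSS total
#'
#' The severity class as an integer grade: none = 0, mild = 1, moderate = 2,
#' severe = 3 — the scale against which ultrasound parameters are
#' correlated and the grade fed to the image simulator.
#'
#' @param total SSS total (0-9).
#' @return Integer vector in 0:3.
#' @export
steatosis_grade <- function(total) {
  as.integer(sss_class(total)) - 1L
}

#' Diagnostic screening metrics
#'
#' Confusion counts of a binary screen against a reference truth, and the
#' standard rates: sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/N, positive predictive value TP/(TP+FP). Rates with a zero
#' denominator are reported as `NA`.
#'
#' @param truth Logical vector: reference-standard disease presence (for
#'   steatosis, SSS total >= 1).
#' @param predicted Logical vector: screen positivity, same length.
#' @param cutoff Optional cutoff value recorded with the result.
#' @return A `screening_result` (see [tidy.screening_result()]).
#' @export
screening_metrics <- function(truth, predicted, cutoff = NA_real_) {
  if (length(truth) == 0L || length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must be non-empty and of equal length.")
  }
  truth <- as.logical(truth)
  predicted <- as.logical(predicted)
  tp <- sum(truth & predicted)
  fp <- sum(!truth & predicted)
  tn <- sum(!truth & !predicted)
  fn <- sum(truth & !predicted)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  structure(
    list(
      tp = tp, fp = fp, tn = tn, fn = fn, n = length(truth),
      sensitivity = rate(tp, tp + fn),
      specificity = rate(tn, tn + fp),
      accuracy = rate(tp + tn, length(truth)),
      ppv = rate(tp, tp + fp),
      cutoff = cutoff
    ),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<screening_result> n = %d (TP %d, FP %d, TN %d, FN %d)\n",
      "  sensitivity %.3f  specificity %.3f  accuracy %.3f  PPV %.3f\n"
    ),
    x$n, x$tp, x$fp, x$tn, x$fn,
    x$sensitivity, x$specificity, x$accuracy, x$ppv
  ))
  if (!is.na(x$cutoff)) cat(sprintf("  cutoff > %g\n", x$cutoff))
  invisible(x)
}

#' Data-derived screening cutoff
#'
#' The cutoff is the maximum of the continuous measure over a reference
#' subset (e.g. the histologically healthy animals), and the classification
#' rule is strictly greater-than. The strict inequality makes the reference
#' maximum itself classify negative, so the cutoff yields 100% specificity
#' on its own reference set by construction.
#'
#' @param values Per-subject continuous measure (e.g. hepatorenal index).
#' @param reference Logical vector selecting the reference subset.
#' @return The cutoff value, with the classification rule in
#'   `attr(, "rule")`.
#' @export
derive_cutoff <- function(values, reference) {
  if (length(values) != length(reference)) {
    abort("`values` and `reference` must have equal length.")
  }
  if (!any(reference)) abort("Reference subset is empty.")
  cutoff <- max(values[reference])
  attr(cutoff, "rule") <- "positive iff value > cutoff"
  cutoff
}

#' Indeterminate zone of a continuous screen
#'
#' The overlap interval between classes: from the minimum of the measure
#' over diseased subjects to the maximum over healthy subjects. When the
#' classes separate (low > high) the interval is empty.
#'
#' @param values Per-subject continuous measure.
#' @param truth Logical disease-presence labels.
#' @return Tibble with `low`, `high`, `empty`.
#' @export
indeterminate_zone <- function(values, truth) {
  truth <- as.logical(truth)
  if (!any(truth) || !any(!truth)) abort("Both classes must be represented.")
  low <- min(values[truth])
  high <- max(values[!truth])
  tibble::tibble(low = low, high = high, empty = low > high)
}

#' Tie-corrected Spearman rank correlation
#'
#' Average ranks for ties, `r` = Pearson correlation of the rank vectors,
#' two-sided p from the t approximation `t = r sqrt((n-2)/(1-r^2))` on
#' `n - 2` df, and a 95% confidence interval via the Fisher z transform with
#' SE `1/sqrt(n-3)`. Significance is judged against the
#' Bonferroni-adjusted level `alpha / n_tests`.
#'
#' @param x,y Equal-length numeric/ordinal vectors, `n >= 4`.
#' @param n_tests Size of the test family for the Bonferroni adjustment.
#' @param alpha Family-wise level (default 0.05).
#' @return A `spearman_cor` object (see [tidy.spearman_cor()]).
#' @export
spearman_cor <- function(x, y, n_tests = 1, alpha = 0.05) {
  n <- length(x)
  if (n < 4L || length(y) != n) {
    abort("`x` and `y` must have equal length n >= 4.")
  }
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort("Undefined correlation: zero rank variance.")
  }
  r <- cor(rx, ry)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  half <- qnorm(0.975) / sqrt(n - 3)
  adj_alpha <- bonferroni_alpha(alpha, n_tests)
  structure(
    list(
      estimate = r, n = n, p = p,
      ci_low = tanh(z - half), ci_high = tanh(z + half),
      alpha = adj_alpha, n_tests = n_tests,
      significant = p < adj_alpha
    ),
    class = "spearman_cor"
  )
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf(
    "<spearman_cor> r = %.4f (95%% CI %.4f-%.4f), n = %d, p = %.3g%s\n",
    x$estimate, x$ci_low, x$ci_high, x$n, x$p,
    if (x$significant) sprintf(" (significant at %.5g)", x$alpha) else ""
  ))
  invisible(x)
}

#' Bonferroni-adjusted significance threshold
#'
#' `alpha / m` for a family of `m` tests; the study's six-test family (CUS,
#' HRI, and four texture features against histology) gives 0.05/6 = 0.00833.
#'
#' @param family_alpha Family-wise level.
#' @param m Number of tests (>= 1).
#' @return Adjusted per-test threshold.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, m = 1) {
  if (m < 1) abort("`m` must be >= 1.")
  family_alpha / m
}

#' Min-max normalization to \[0, 1\]
#'
#' `(v - min) / (max - min)`; a monotone map, so rank order is preserved. A
#' constant vector maps to all 0.5 and is flagged via
#' `attr(, "degenerate")`.
#'
#' @param values Numeric vector of length >= 2.
#' @return Normalized vector.
#' @export
minmax_normalize <- function(values) {
  if (length(values) < 2L) abort("Need >= 2 values.")
  rng <- range(values)
  if (rng[1] == rng[2]) {
    out <- rep(0.5, length(values))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (values - rng[1]) / (rng[2] - rng[1])
  attr(out, "degenerate") <- FALSE
  out
}

#' Percent change between group means
#'
#' `(test / reference - 1) * 100`.
#'
#' @param reference Reference group mean (non-zero).
#' @param test Test group mean.
#' @return Percent difference.
#' @export
percent_change <- function(reference, test) {
  if (any(reference == 0)) abort("Zero reference mean.")
  (test / reference - 1) * 100
}
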