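#' Tidy a screening result
#'
#' @param x A `screening_result` from [screening_metrics()].
#' @param ... Unused.
#' @return A tibble with one row per metric (`sensitivity`, `specificity`,
#'   `accuracy`, `ppv`) and its `estimate`.
#' @export
tidy.screening_result <- function(x, ...) {
  tibble::tibble(
    metric = c("sensitivity", "specificity", "accuracy", "ppv"),
    estimate = c(x$sensitivity, x$specificity, x$accuracy, x$ppv)
  )
}

#' @rdname tidy.screening_result
#' @return `glance()`: a one-row tibble with the confusion counts, the four
#'   rates, `n`, and the cutoff (if any).
#' @export
glance.screening_result <- function(x, ...) {
  tibble::tibble(
    tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn, n = x$n,
    sensitivity = x$sensitivity, specificity = x$specificity,
    accuracy = x$accuracy, ppv = x$ppv, cutoff = x$cutoff
  )
}

#' Tidy a Spearman correlation result
#'
#' @param x A `spearman_cor` from [spearman_cor()].
#' @param ... Unused.
#' @return One-row tibble: `estimate`, `ci_low`, `ci_high`, `p.value`,
#'   `n`, `alpha`, `significant`.
#' @export
tidy.spearman_cor <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate, ci_low = x$ci_low, ci_high = x$ci_high,
    p.value = x$p, n = x$n, alpha = x$alpha, significant = x$significant
  )
}

#' @rdname tidy.spearman_cor
#' @export
glance.spearman_cor <- function(x, ...) tidy.spearman_cor(x)
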