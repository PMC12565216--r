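#' Plot a screening confusion matrix
#'
#' @param object A `screening_result` from [screening_metrics()].
#' @param ... Unused.
#' @return A ggplot: 2 x 2 confusion tile plot annotated with counts.
#' @export
autoplot.screening_result <- function(object, ...) {
  df <- tibble::tibble(
    truth = factor(c("present", "present", "absent", "absent"),
                   levels = c("present", "absent")),
    predicted = factor(c("positive", "negative", "positive", "negative"),
                       levels = c("positive", "negative")),
    n = c(object$tp, object$fn, object$fp, object$tn)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth, fill = .data$n)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 5) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      x = "Ultrasound screen", y = "Histology",
      title = sprintf(
        "Sens %.0f%% / Spec %.0f%% / PPV %.0f%%",
        100 * object$sensitivity, 100 * object$specificity, 100 * object$ppv
      )
    ) +
    ggplot2::theme_minimal()
}

#' Min-max normalized texture features by severity class
#'
#' Box plots of the four GLCM features, each normalized to \[0, 1\] across
#' the cohort, split by histological severity class.
#'
#' @param cohort Cohort tibble with `steatosis_class` and the four feature
#'   columns (e.g. from [run_pipeline()]`$cohort`).
#' @return A ggplot.
#' @export
plot_feature_distributions <- function(cohort) {
  feats <- c("contrast", "correlation", "energy", "sum_entropy")
  long <- cohort |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(feats), ~ as.numeric(minmax_normalize(.x))
    )) |>
    tidyr::pivot_longer(dplyr::all_of(feats),
                        names_to = "feature", values_to = "normalized")
  ggplot2::ggplot(long, ggplot2::aes(.data$steatosis_class, .data$normalized)) +
    ggplot2::geom_boxplot(fill = "grey85", outlier.size = 0.8) +
    ggplot2::facet_wrap(~feature, nrow = 1) +
    ggplot2::labs(x = "Histological severity", y = "Normalized value (0-1)") +
    ggplot2::theme_minimal()
}

#' Hepatorenal index by severity class
#'
#' @param cohort Cohort tibble with `steatosis_class` and `hri`.
#' @param cutoff Optional screening cutoff drawn as a horizontal line.
#' @return A ggplot.
#' @export
plot_hri_by_class <- function(cohort, cutoff = NULL) {
  p <- ggplot2::ggplot(cohort, ggplot2::aes(.data$steatosis_class, .data$hri)) +
    ggplot2::geom_boxplot(fill = "grey85", outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, size = 1) +
    ggplot2::labs(x = "Histological severity", y = "Hepatorenal index") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = 2, color = "firebrick")
  }
  p
}
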