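#' Mean gray level of a circular ROI
#'
#' First-order gray-level-histogram statistic: the arithmetic mean of the
#' raw (pre-discretization) display levels inside the disk.
#'
#' @param image A [bmode_image()].
#' @param roi A [circular_roi()] bound to `image`.
#' @return Mean gray level (numeric scalar).
#' @export
roi_mean_intensity <- function(image, roi) {
  v <- roi_values(image, roi)
  if (length(v) == 0L) abort("Empty ROI.")
  mean(v)
}

#' Hepatorenal index
#'
#' `HRI = liver_mean / renal_mean`: caudate-lobe echogenicity normalized to
#' the right renal cortex. Because both ROIs scale together under a gain
#' change, the ratio compensates for variability in scanning parameters.
#'
#' @param liver_mean Mean gray level of the liver (caudate lobe) ROI.
#' @param renal_mean Mean gray level of the renal-cortex ROI (> 0).
#' @param subject,age_weeks Optional identifiers carried into the result.
#' @return One-row tibble with `liver_mean`, `renal_mean`, `hri` (and the
#'   identifiers when given).
#' @export
compute_hri <- function(liver_mean, renal_mean, subject = NA_character_,
                        age_weeks = NA_real_) {
  if (renal_mean <= 0) abort("Degenerate denominator: renal mean must be > 0.")
  tibble::tibble(
    subject = subject, age_weeks = age_weeks,
    liver_mean = liver_mean, renal_mean = renal_mean,
    hri = liver_mean / renal_mean
  )
}

#' Hepatorenal index from one frame
#'
#' Both ROIs are read off the same frame (the standard liver/kidney view),
#' using raw 0-255 display levels.
#'
#' @param image A [bmode_image()].
#' @param liver_roi,renal_roi [circular_roi()]s for the caudate lobe and the
#'   right renal cortex.
#' @inheritParams compute_hri
#' @return One-row tibble (see [compute_hri()]).
#' @export
hri_from_image <- function(image, liver_roi, renal_roi,
                           subject = NA_character_, age_weeks = NA_real_) {
  compute_hri(
    roi_mean_intensity(image, liver_roi),
    roi_mean_intensity(image, renal_roi),
    subject = subject, age_weeks = age_weeks
  )
}
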