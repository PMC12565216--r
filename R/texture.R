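#' Gray-level co-occurrence matrix
#'
#' Accumulates counts over all ordered in-mask pixel pairs at each offset,
#' pools the directions into one matrix, symmetrizes (each pair counted as
#' (i, j) and (j, i)) and normalizes to sum 1. Pairs with either pixel
#' outside the mask (`NA` level) are excluded. The default offsets are the
#' four 2D directions at distance 1 — right, down, down-right, down-left —
#' pooled before normalization.
#'
#' @param levels Integer level grid in `[0, Ng - 1]`; `NA` marks pixels
#'   outside the ROI mask.
#' @param distance_px Offset magnitude (default 1).
#' @param directions List of `(drow, dcol)` integer offsets.
#' @param n_levels Matrix size `Ng`; defaults to `max(levels) + 1`.
#' @return A `glcm`: list with probability matrix `p` (`Ng x Ng`), `n_levels`,
#'   `n_pairs`, `distance_px`, `directions`, `symmetric = TRUE`.
#' @export
build_glcm <- function(levels,
                       distance_px = 1,
                       directions = list(c(0, 1), c(1, 0), c(1, 1), c(1, -1)),
                       n_levels = NULL) {
  if (!is.matrix(levels)) abort("`levels` must be a matrix.")
  vals <- levels[!is.na(levels)]
  if (length(vals) < 2L) abort("Need >= 2 in-mask pixels.")
  if (any(vals < 0)) abort("Levels must be non-negative integers.")
  ng <- n_levels %||% (max(vals) + 1L)
  ng <- as.integer(ng)
  nr <- nrow(levels)
  nc <- ncol(levels)
  counts <- matrix(0, ng, ng)
  n_pairs <- 0L
  for (d in directions) {
    dr <- as.integer(d[1] * distance_px)
    dc <- as.integer(d[2] * distance_px)
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    if (length(r1) == 0L || length(c1) == 0L) next
    a <- levels[r1, c1, drop = FALSE]
    b <- levels[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    i <- a[ok]
    j <- b[ok]
    idx <- i * ng + j + 1L
    tab <- tabulate(idx, nbins = ng * ng)
    counts <- counts + matrix(tab, ng, ng, byrow = TRUE)
    n_pairs <- n_pairs + length(i)
  }
  if (n_pairs == 0L) abort("Empty GLCM: no valid in-mask pixel pair at any offset.")
  counts <- counts + t(counts)
  structure(
    list(
      p = counts / sum(counts), n_levels = ng, n_pairs = n_pairs,
      distance_px = distance_px, directions = directions, symmetric = TRUE
    ),
    class = "glcm"
  )
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf(
    "<glcm> %d x %d, %d ordered pairs, distance %g, %d direction(s), symmetric\n",
    x$n_levels, x$n_levels, x$n_pairs, x$distance_px, length(x$directions)
  ))
  invisible(x)
}

#' Second-order texture features of a GLCM
#'
#' The four features used for hepatic-steatosis texture analysis, with
#' 0-based gray-level indices `i, j` and co-occurrence probabilities
#' `p(i, j)`:
#' \describe{
#'   \item{contrast}{`sum p(i,j) (i - j)^2` — local intensity variation.}
#'   \item{correlation}{`(sum i j p(i,j) - mu_x mu_y) / (sigma_x sigma_y)` —
#'     linear dependency of neighboring levels; `NA` when a single level
#'     occupies the matrix (zero marginal SD).}
#'   \item{energy}{`sum p(i,j)^2` (angular second moment) — uniformity.}
#'   \item{sum_entropy}{`-sum p_{x+y}(k) log2 p_{x+y}(k)` over the
#'     diagonal-sum marginal `p_{x+y}(k) = sum_{i+j=k} p(i,j)`, with
#'     `0 log 0 = 0`; log base 2 (bits).}
#' }
#' For a symmetric GLCM the two marginals coincide, so `mu_x = mu_y`.
#'
#' @param glcm A [build_glcm()] result.
#' @return One-row tibble with columns `contrast`, `correlation`, `energy`,
#'   `sum_entropy`.
#' @export
texture_features <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  p <- glcm$p
  ng <- glcm$n_levels
  lv <- 0:(ng - 1)
  px <- rowSums(p)
  mu <- sum(lv * px)
  sig2 <- sum((lv - mu)^2 * px)

  diffs2 <- outer(lv, lv, function(i, j) (i - j)^2)
  contrast <- sum(p * diffs2)
  energy <- sum(p^2)
  correlation <- if (sig2 > 0) {
    (sum(outer(lv, lv) * p) - mu^2) / sig2
  } else {
    NA_real_
  }
  ksum <- as.vector(outer(lv, lv, `+`))
  pxy <- vapply(
    split(as.vector(p), ksum),
    sum, numeric(1)
  )
  pxy <- pxy[pxy > 0]
  sum_entropy <- -sum(pxy * log2(pxy))

  tibble::tibble(
    contrast = contrast, correlation = correlation,
    energy = energy, sum_entropy = sum_entropy
  )
}

#' Extract the four texture features from an image ROI
#'
#' Runs the full conditioning chain ([preprocess_roi()]) and the GLCM on one
#' circular ROI of a B-mode frame.
#'
#' @inheritParams smooth_roi
#' @param distance_px,directions Passed to [build_glcm()].
#' @return One-row tibble of features (see [texture_features()]).
#' @export
extract_features <- function(image, roi, params = preprocess_params(),
                             distance_px = 1,
                             directions = list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
  pp <- preprocess_roi(image, roi, params)
  g <- build_glcm(pp$levels, distance_px = distance_px,
                  directions = directions, n_levels = params$n_gray_levels)
  texture_features(g)
}

#' Average per-lobe features into a per-subject record
#'
#' Texture features are computed per scanned liver lobe and averaged per
#' animal. Undefined correlations (single-level ROIs) are excluded from the
#' correlation mean and counted.
#'
#' @param features Tibble with one row per lobe image and columns `contrast`,
#'   `correlation`, `energy`, `sum_entropy` (extra columns ignored).
#' @return One-row tibble of the per-feature arithmetic means plus
#'   `n_lobes` and `n_undefined_correlation`.
#' @export
features_for_subject <- function(features) {
  if (nrow(features) < 1L) abort("Need >= 1 lobe feature set.")
  tibble::tibble(
    contrast = mean(features$contrast),
    correlation = if (all(is.na(features$correlation))) NA_real_ else {
      mean(features$correlation, na.rm = TRUE)
    },
    energy = mean(features$energy),
    sum_entropy = mean(features$sum_entropy),
    n_lobes = nrow(features),
    n_undefined_correlation = sum(is.na(features$correlation))
  )
}
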