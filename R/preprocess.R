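#' Pre-extraction conditioning parameters
#'
#' Defaults reproduce the texture workflow's published settings: Gaussian
#' smoothing at 0.018 mm with reflect padding on the exact ROI bounding box,
#' intensity correction at mean +/- 3 SD, and relative (min-max) rescaling
#' into 256 gray levels. The 0.018 mm scale is interpreted as the Gaussian
#' sigma per axis (about 1 pixel at the stated spacing); a full-width
#' interpretation would halve it, and the source tooling does not say which
#' is meant.
#'
#' @param gaussian_kernel_mm Gaussian sigma per axis (mm); >= 0.
#' @param clip_k SD multiplier for intensity correction (> 0).
#' @param n_gray_levels Number of discretization bins (>= 2).
#' @param padding Boundary rule for smoothing; only `"reflect"` is
#'   implemented.
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(gaussian_kernel_mm = 0.018, clip_k = 3,
                              n_gray_levels = 256, padding = "reflect") {
  if (gaussian_kernel_mm < 0) abort("`gaussian_kernel_mm` must be >= 0.")
  if (clip_k <= 0) abort("`clip_k` must be > 0.")
  if (n_gray_levels < 2) abort("`n_gray_levels` must be >= 2.")
  padding <- match.arg(padding, "reflect")
  structure(
    list(
      gaussian_kernel_mm = gaussian_kernel_mm, clip_k = clip_k,
      n_gray_levels = as.integer(n_gray_levels), padding = padding
    ),
    class = "preprocess_params"
  )
}

# Half-sample-symmetric reflection of an out-of-range index into 1..n.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  i <- ((i - 1L) %% period + period) %% period
  ifelse(i < n, i + 1L, period - i)
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  radius <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-radius):radius / sigma)^2)
  k / sum(k)
}

# Separable Gaussian smoothing with reflect boundary; conserves the total
# sum exactly (the folded convolution operator is doubly stochastic).
gaussian_smooth <- function(mat, sigma_row, sigma_col) {
  smooth_axis <- function(m, sigma, by_row) {
    k <- gaussian_kernel_1d(sigma)
    if (length(k) == 1L) return(m)
    radius <- (length(k) - 1L) %/% 2L
    n <- if (by_row) nrow(m) else ncol(m)
    idx <- reflect_index((1L - radius):(n + radius), n)
    padded <- if (by_row) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
    out <- m * 0
    for (u in seq_along(k)) {
      block <- if (by_row) {
        padded[u:(u + n - 1L), , drop = FALSE]
      } else {
        padded[, u:(u + n - 1L), drop = FALSE]
      }
      out <- out + k[u] * block
    }
    out
  }
  smooth_axis(smooth_axis(mat, sigma_row, by_row = TRUE), sigma_col, by_row = FALSE)
}

roi_patch <- function(image, roi) {
  bind_roi(image, roi)
  rr <- range(roi$pixels$row)
  cc <- range(roi$pixels$col)
  patch <- image$pixels[(rr[1] + 1L):(rr[2] + 1L), (cc[1] + 1L):(cc[2] + 1L),
                        drop = FALSE]
  mask <- matrix(FALSE, nrow(patch), ncol(patch))
  mask[cbind(roi$pixels$row - rr[1] + 1L, roi$pixels$col - cc[1] + 1L)] <- TRUE
  list(patch = patch * 1.0, mask = mask, row0 = rr[1], col0 = cc[1])
}

#' Smooth an ROI patch
#'
#' Applies a Gaussian low-pass filter (sigma = `gaussian_kernel_mm` / pixel
#' spacing per axis) to the exact bounding box of the circular ROI with
#' reflect boundary handling; pixels outside the disk are masked (`NA`)
#' after filtering, so the disk geometry is preserved for downstream
#' adjacency analysis.
#'
#' @param image A [bmode_image()].
#' @param roi A [circular_roi()] bound to `image`.
#' @param params A [preprocess_params()].
#' @return List with `patch` (real-valued matrix, `NA` outside the disk),
#'   `mask`, and the bounding-box origin `row0`, `col0` (0-based).
#' @export
smooth_roi <- function(image, roi, params = preprocess_params()) {
  p <- roi_patch(image, roi)
  sigma_row <- params$gaussian_kernel_mm / image$spacing_y_mm
  sigma_col <- params$gaussian_kernel_mm / image$spacing_x_mm
  if (params$gaussian_kernel_mm > 0 && min(sigma_row, sigma_col) < 0.25) {
    warn(sprintf(
      "Gaussian sigma is %.3f px; the filter is close to identity.",
      min(sigma_row, sigma_col)
    ))
  }
  sm <- gaussian_smooth(p$patch, sigma_row, sigma_col)
  sm[!p$mask] <- NA_real_
  list(patch = sm, mask = p$mask, row0 = p$row0, col0 = p$col0)
}

#' Winsorize patch intensities at mean +/- k SD
#'
#' Values below `mu - k sigma` are set to `mu - k sigma` and values above
#' `mu + k sigma` to `mu + k sigma`, where `mu` and `sigma` are the mean and
#' population SD of the (unmasked) patch values before clipping. A constant
#' patch (`sigma = 0`) is returned unchanged. Clipping rather than excluding
#' outlier pixels preserves the ROI geometry for co-occurrence adjacency.
#'
#' @param patch Numeric matrix or vector; `NA` marks masked-out pixels.
#' @param clip_k SD multiplier (default 3).
#' @return The clipped patch, same shape, masked pixels still `NA`.
#' @export
clip_outliers <- function(patch, clip_k = 3) {
  v <- patch[!is.na(patch)]
  if (length(v) < 2L) abort("Need >= 2 unmasked pixels to clip outliers.")
  if (!all(is.finite(v))) abort("Patch values must be finite.")
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  if (sigma == 0) return(patch)
  pmin(pmax(patch, mu - clip_k * sigma), mu + clip_k * sigma)
}

#' Relative (min-max) gray-level discretization
#'
#' `level = floor((v - vmin) / (vmax - vmin) * n)` with `v = vmax` mapped to
#' `n - 1` (half-open bins, top edge closed). Because binning is relative to
#' the patch range, the level grid is invariant to positive affine intensity
#' transforms, decoupling the texture features from gain and acquisition
#' settings. A constant patch maps to all-zero levels and is flagged via
#' `attr(, "degenerate")`.
#'
#' @param patch Numeric matrix or vector; `NA` marks masked-out pixels.
#' @param n_gray_levels Number of bins (default 256).
#' @return Integer level grid in `[0, n - 1]`, `NA` preserved.
#' @export
discretize <- function(patch, n_gray_levels = 256) {
  v <- patch[!is.na(patch)]
  if (length(v) == 0L) abort("Patch has no unmasked pixels.")
  vmin <- min(v)
  vmax <- max(v)
  if (vmax == vmin) {
    out <- patch
    out[!is.na(out)] <- 0
    storage.mode(out) <- "integer"
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  lev <- floor((patch - vmin) / (vmax - vmin) * n_gray_levels)
  lev <- pmin(lev, n_gray_levels - 1L)
  storage.mode(lev) <- "integer"
  attr(lev, "degenerate") <- FALSE
  lev
}

#' Full ROI conditioning chain
#'
#' Fixed order: smooth, then winsorize, then discretize. (Permuting the clip
#' and discretize stages changes the result; the order is part of the
#' workflow contract.)
#'
#' @inheritParams smooth_roi
#' @return List with `levels` (integer grid, `NA` outside the disk), `mask`,
#'   and `degenerate` flag.
#' @export
preprocess_roi <- function(image, roi, params = preprocess_params()) {
  sm <- smooth_roi(image, roi, params)
  clipped <- clip_outliers(sm$patch, params$clip_k)
  levels <- discretize(clipped, params$n_gray_levels)
  list(
    levels = levels, mask = sm$mask,
    degenerate = isTRUE(attr(levels, "degenerate"))
  )
}
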