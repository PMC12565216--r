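#' Circular region of interest
#'
#' Rasterizes the disk of nominal area `nominal_area_px` centered at the given
#' pixel: radius `r = sqrt(nominal_area_px / pi)`, and a pixel belongs iff its
#' center lies at Euclidean distance <= r from the ROI center. This
#' center-in-disk rule is deterministic, so the realized pixel count can
#' deviate slightly from the nominal area (a 100-pixel ROI rasterizes to 97
#' pixels). Coordinates are 0-based `(row, col)`.
#'
#' @param center_row,center_col ROI center, 0-based pixel coordinates.
#' @param nominal_area_px Target pixel count (>= 1); the standard texture ROI
#'   uses 100.
#' @return A `circular_roi`: list with `center_row`, `center_col`,
#'   `nominal_area_px`, `radius_px`, and `pixels`, a tibble of 0-based
#'   `(row, col)` members.
#' @export
circular_roi <- function(center_row, center_col, nominal_area_px = 100) {
  if (nominal_area_px < 1) abort("`nominal_area_px` must be >= 1.")
  r <- sqrt(nominal_area_px / pi)
  span <- ceiling(r)
  grid <- expand.grid(
    row = center_row + (-span:span),
    col = center_col + (-span:span)
  )
  d2 <- (grid$row - center_row)^2 + (grid$col - center_col)^2
  keep <- d2 <= r^2 + 1e-12
  pixels <- tibble::tibble(row = grid$row[keep], col = grid$col[keep])
  structure(
    list(
      center_row = center_row, center_col = center_col,
      nominal_area_px = nominal_area_px, radius_px = r,
      pixels = pixels
    ),
    class = "circular_roi"
  )
}

#' @export
print.circular_roi <- function(x, ...) {
  cat(sprintf(
    "<circular_roi> center (%g, %g), nominal %g px, rasterized %d px (r = %.3f px)\n",
    x$center_row, x$center_col, x$nominal_area_px, nrow(x$pixels), x$radius_px
  ))
  invisible(x)
}

#' Check that an ROI lies inside an image
#'
#' @param image A [bmode_image()].
#' @param roi A [circular_roi()].
#' @return `roi`, invisibly, if fully inside; otherwise an error listing the
#'   clipped pixels.
#' @export
bind_roi <- function(image, roi) {
  stopifnot(inherits(image, "bmode_image"), inherits(roi, "circular_roi"))
  nr <- nrow(image$pixels)
  nc <- ncol(image$pixels)
  out <- roi$pixels$row < 0 | roi$pixels$row >= nr |
    roi$pixels$col < 0 | roi$pixels$col >= nc
  if (any(out)) {
    bad <- roi$pixels[out, , drop = FALSE]
    abort(sprintf(
      "ROI extends outside the %d x %d image; %d clipped pixel(s): %s",
      nr, nc, nrow(bad),
      paste(sprintf("(%d,%d)", bad$row, bad$col), collapse = " ")
    ))
  }
  invisible(roi)
}

roi_values <- function(image, roi) {
  bind_roi(image, roi)
  image$pixels[cbind(roi$pixels$row + 1L, roi$pixels$col + 1L)]
}

#' Read / write a circular-ROI sidecar
#'
#' Sidecars are JSON objects `{center_row, center_col, nominal_area_px}`
#' (0-based pixel coordinates).
#'
#' @param path JSON file path.
#' @return [read_roi()] returns a [circular_roi()]; [write_roi()] returns
#'   `path` invisibly.
#' @export
read_roi <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  circular_roi(spec$center_row, spec$center_col, spec$nominal_area_px)
}

#' @rdname read_roi
#' @param roi A [circular_roi()].
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "circular_roi"))
  jsonlite::write_json(
    list(
      center_row = roi$center_row, center_col = roi$center_col,
      nominal_area_px = roi$nominal_area_px
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
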