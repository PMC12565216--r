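#' B-mode image constructor
#'
#' A `bmode_image` holds a single 2D 8-bit grayscale ultrasound frame together
#' with its physical pixel spacing and free-form acquisition metadata. Gray
#' levels are integers in \[0, 255\]; spacings are in mm/pixel. Coordinates
#' are 0-based `(row, col)` with rows increasing downward.
#'
#' When spacing is not available from the source file, the resampling
#' constants used by the texture workflow (x = 0.017578 mm, y = 0.0176 mm)
#' are substituted and flagged in `meta$spacing_assumed`.
#'
#' @param pixels Integer matrix of gray levels in \[0, 255\].
#' @param spacing_x_mm,spacing_y_mm Physical pixel spacing (mm/pixel),
#'   strictly positive. x is the column direction, y the row direction.
#' @param meta Named list of acquisition metadata (subject id, age in weeks,
#'   liver lobe, gain dB, dynamic range dB, ...).
#' @return An object of class `bmode_image`.
#' @export
bmode_image <- function(pixels,
                        spacing_x_mm = 0.017578,
                        spacing_y_mm = 0.0176,
                        meta = list()) {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    abort("`pixels` must be a non-empty matrix.")
  }
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || any(pixels < 0L) || any(pixels > 255L)) {
    abort("All gray levels must be integers in [0, 255].")
  }
  if (!is.numeric(spacing_x_mm) || spacing_x_mm <= 0 ||
      !is.numeric(spacing_y_mm) || spacing_y_mm <= 0) {
    abort("Pixel spacings must be strictly positive (mm/pixel).")
  }
  structure(
    list(
      pixels = pixels,
      spacing_x_mm = as.numeric(spacing_x_mm),
      spacing_y_mm = as.numeric(spacing_y_mm),
      meta = meta
    ),
    class = "bmode_image"
  )
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf(
    "<bmode_image> %d x %d px, spacing %.6g x %.6g mm, gray [%d, %d]\n",
    nrow(x$pixels), ncol(x$pixels), x$spacing_x_mm, x$spacing_y_mm,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' @export
dim.bmode_image <- function(x) dim(x$pixels)

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = "tiff",
    png = "png",
    dcm = , dicom = "dicom",
    abort(sprintf("Cannot guess image format from extension '%s'.", ext))
  )
}

#' Read a grayscale B-mode frame
#'
#' Reads an 8-bit grayscale image from TIFF, PNG, or single-frame DICOM.
#' Color or multi-frame inputs are rejected. TIFF/PNG carry no physical
#' spacing, so the default resampling constants are used and flagged; DICOM
#' spacing is read from the PixelSpacing tag when present.
#'
#' @param path Path to the image file.
#' @param format One of `"tiff"`, `"png"`, `"dicom"`; guessed from the file
#'   extension when `NULL`.
#' @return A [bmode_image()].
#' @export
read_bmode <- function(path, format = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("tiff", "png", "dicom"))
  if (format == "dicom") {
    return(read_dicom_gray(path))
  }
  raw <- switch(format,
    tiff = tiff::readTIFF(path, all = TRUE),
    png = png::readPNG(path)
  )
  if (format == "tiff") {
    if (length(raw) != 1L) {
      abort(sprintf("Unsupported format: multi-frame TIFF (%d frames).", length(raw)))
    }
    raw <- raw[[1L]]
  }
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] == 1L) {
      raw <- raw[, , 1L]
    } else {
      abort(sprintf(
        "Unsupported format: color image with %d channels; expected grayscale.",
        dim(raw)[3]
      ))
    }
  }
  px <- matrix(as.integer(round(raw * 255)), nrow(raw), ncol(raw))
  bmode_image(px, meta = list(source = path, spacing_assumed = TRUE))
}

#' Write a grayscale B-mode frame
#'
#' Inverse of [read_bmode()]: `read_bmode(write_bmode(img, path))` returns the
#' identical pixel grid for all three formats.
#'
#' @param image A [bmode_image()].
#' @param path Output path.
#' @param format One of `"tiff"`, `"png"`, `"dicom"`; guessed from the
#'   extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_bmode <- function(image, path, format = NULL) {
  stopifnot(inherits(image, "bmode_image"))
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("tiff", "png", "dicom"))
  if (format == "dicom") {
    write_dicom_gray(image, path)
  } else {
    scaled <- image$pixels / 255
    switch(format,
      tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 8L),
      png = png::writePNG(scaled, path)
    )
  }
  invisible(path)
}
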