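# Minimal DICOM I/O for the one profile the pipeline touches: single-frame,
# 8-bit, MONOCHROME2, Explicit VR Little Endian. Anything else is rejected
# with an error naming the offense. PixelSpacing is (row, column) spacing in
# mm, i.e. (y, x).

DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_SOP_US_IMAGE <- "1.2.840.10008.5.1.4.1.1.6.1"
DICOM_IMPL_UID <- "1.2.826.0.1.3680043.8.498.1"

uint16le <- function(x) as.raw(c(x %% 256L, x %/% 256L))
uint32le <- function(x) {
  as.raw(c(x %% 256L, (x %/% 256L) %% 256L, (x %/% 65536L) %% 256L, x %/% 16777216L))
}

dcm_pad_even <- function(value, pad = as.raw(0x20)) {
  if (length(value) %% 2L == 1L) c(value, pad) else value
}

# Explicit-VR element encoding; OB takes the long (reserved + 4-byte) form.
dcm_element <- function(group, elem, vr, value) {
  if (is.character(value)) value <- charToRaw(value)
  if (vr %in% c("UI")) value <- dcm_pad_even(value, as.raw(0x00))
  if (vr %in% c("CS", "DS", "IS", "LO", "SH")) value <- dcm_pad_even(value)
  head <- c(uint16le(group), uint16le(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "UT", "UN", "SQ")) {
    if (length(value) %% 2L == 1L) value <- c(value, as.raw(0x00))
    c(head, as.raw(c(0, 0)), uint32le(length(value)), value)
  } else {
    c(head, uint16le(length(value)), value)
  }
}

write_dicom_gray <- function(image, path) {
  stopifnot(inherits(image, "bmode_image"))
  px <- image$pixels
  # DICOM pixel data is row-major; R matrices are column-major.
  pixel_bytes <- as.raw(as.integer(t(px)))
  spacing <- sprintf("%.8g\\%.8g", image$spacing_y_mm, image$spacing_x_mm)
  sop_instance <- paste0(DICOM_IMPL_UID, ".1")

  meta <- c(
    dcm_element(0x0002L, 0x0001L, "OB", as.raw(c(0x00, 0x01))),
    dcm_element(0x0002L, 0x0002L, "UI", DICOM_SOP_US_IMAGE),
    dcm_element(0x0002L, 0x0003L, "UI", sop_instance),
    dcm_element(0x0002L, 0x0010L, "UI", DICOM_TS_EXPLICIT_LE),
    dcm_element(0x0002L, 0x0012L, "UI", DICOM_IMPL_UID)
  )
  dataset <- c(
    dcm_element(0x0008L, 0x0016L, "UI", DICOM_SOP_US_IMAGE),
    dcm_element(0x0008L, 0x0018L, "UI", sop_instance),
    dcm_element(0x0028L, 0x0002L, "US", uint16le(1L)),
    dcm_element(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
    dcm_element(0x0028L, 0x0008L, "IS", "1"),
    dcm_element(0x0028L, 0x0010L, "US", uint16le(nrow(px))),
    dcm_element(0x0028L, 0x0011L, "US", uint16le(ncol(px))),
    dcm_element(0x0028L, 0x0030L, "DS", spacing),
    dcm_element(0x0028L, 0x0100L, "US", uint16le(8L)),
    dcm_element(0x0028L, 0x0101L, "US", uint16le(8L)),
    dcm_element(0x0028L, 0x0102L, "US", uint16le(7L)),
    dcm_element(0x0028L, 0x0103L, "US", uint16le(0L)),
    dcm_element(0x7FE0L, 0x0010L, "OB", pixel_bytes)
  )
  out <- c(
    raw(128), charToRaw("DICM"),
    dcm_element(0x0002L, 0x0000L, "UL", uint32le(length(meta))),
    meta, dataset
  )
  writeBin(out, path)
  invisible(path)
}

read_uint16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
read_uint32 <- function(raw, pos) {
  sum(as.numeric(raw[pos + 0:3]) * c(1, 256, 65536, 16777216))
}

# Walks Explicit-VR-LE elements starting at `pos`, returning a list of
# (group, elem, value-raw) until end of buffer.
dcm_parse_elements <- function(bytes, pos) {
  out <- list()
  n <- length(bytes)
  while (pos + 7L <= n + 1L && pos <= n - 7L) {
    group <- read_uint16(bytes, pos)
    elem <- read_uint16(bytes, pos + 2L)
    vr <- rawToChar(bytes[pos + 4:5])
    if (vr %in% c("OB", "OW", "OF", "UT", "UN", "SQ")) {
      len <- read_uint32(bytes, pos + 8L)
      val_start <- pos + 12L
    } else if (grepl("^[A-Z]{2}$", vr)) {
      len <- read_uint16(bytes, pos + 6L)
      val_start <- pos + 8L
    } else {
      abort("Unsupported format: DICOM stream is not Explicit VR Little Endian.")
    }
    value <- if (len > 0) bytes[val_start:(val_start + len - 1L)] else raw(0)
    out[[length(out) + 1L]] <- list(group = group, elem = elem, vr = vr, value = value)
    pos <- val_start + len
  }
  out
}

dcm_find <- function(elements, group, elem) {
  for (e in elements) if (e$group == group && e$elem == elem) return(e)
  NULL
}

dcm_string <- function(e) {
  if (is.null(e)) return(NULL)
  v <- e$value[e$value != as.raw(0)]
  sub(" +$", "", rawToChar(v))
}

read_dicom_gray <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM") {
    abort("Unsupported format: not a DICOM part-10 file (missing DICM magic).")
  }
  elements <- dcm_parse_elements(bytes, 133L)
  ts <- dcm_string(dcm_find(elements, 0x0002L, 0x0010L))
  if (!is.null(ts) && ts != DICOM_TS_EXPLICIT_LE) {
    abort(sprintf("Unsupported format: DICOM transfer syntax '%s'.", ts))
  }
  spp <- dcm_find(elements, 0x0028L, 0x0002L)
  if (!is.null(spp) && read_uint16(spp$value, 1L) != 1L) {
    abort(sprintf(
      "Unsupported format: color DICOM (SamplesPerPixel = %d); expected grayscale.",
      read_uint16(spp$value, 1L)
    ))
  }
  nframes <- dcm_string(dcm_find(elements, 0x0028L, 0x0008L))
  if (!is.null(nframes) && as.integer(nframes) > 1L) {
    abort(sprintf("Unsupported format: multi-frame DICOM (%s frames).", nframes))
  }
  bits <- dcm_find(elements, 0x0028L, 0x0100L)
  if (!is.null(bits) && read_uint16(bits$value, 1L) != 8L) {
    abort(sprintf(
      "Unsupported format: %d-bit DICOM; expected 8-bit.", read_uint16(bits$value, 1L)
    ))
  }
  rows <- read_uint16(dcm_find(elements, 0x0028L, 0x0010L)$value, 1L)
  cols <- read_uint16(dcm_find(elements, 0x0028L, 0x0011L)$value, 1L)
  pd <- dcm_find(elements, 0x7FE0L, 0x0010L)
  if (is.null(pd)) abort("DICOM file has no PixelData element.")
  vals <- as.integer(pd$value[seq_len(rows * cols)])
  px <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)

  spacing_str <- dcm_string(dcm_find(elements, 0x0028L, 0x0030L))
  meta <- list(source = path)
  if (!is.null(spacing_str)) {
    sp <- as.numeric(strsplit(spacing_str, "\\\\")[[1]])
    spacing_y <- sp[1]
    spacing_x <- sp[2]
    meta$spacing_assumed <- FALSE
  } else {
    spacing_x <- 0.017578
    spacing_y <- 0.0176
    meta$spacing_assumed <- TRUE
  }
  bmode_image(px, spacing_x_mm = spacing_x, spacing_y_mm = spacing_y, meta = meta)
}
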