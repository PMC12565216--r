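test_that("images round-trip bit-exactly through TIFF, PNG and DICOM", {
  img <- make_test_image(32, 32, seed = 42)
  for (ext in c("tiff", "png", "dcm")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_bmode(img, path)
    back <- read_bmode(path)
    expect_identical(back$pixels, img$pixels, label = ext)
  }
})

test_that("an all-zero TIFF reads back as zeros with the default spacing", {
  path <- withr::local_tempfile(fileext = ".tiff")
  write_bmode(bmode_image(matrix(0L, 4, 4), 0.0176, 0.0176), path)
  img <- read_bmode(path)
  expect_true(all(img$pixels == 0L))
  expect_equal(img$spacing_x_mm, 0.017578)
  expect_true(img$meta$spacing_assumed)
})

test_that("DICOM PixelSpacing survives a round trip and spacing is not flagged", {
  img <- bmode_image(make_test_image(16, 24, seed = 7)$pixels,
                     spacing_x_mm = 0.017578, spacing_y_mm = 0.0176)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_bmode(img, path)
  back <- read_bmode(path)
  expect_equal(back$spacing_x_mm, 0.017578)
  expect_equal(back$spacing_y_mm, 0.0176)
  expect_false(back$meta$spacing_assumed)
})

test_that("DICOM interoperates with an independent reference implementation", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  img <- make_test_image(16, 16, seed = 11)
  ours <- withr::local_tempfile(fileext = ".dcm")
  theirs <- withr::local_tempfile(fileext = ".dcm")
  csv_out <- withr::local_tempfile(fileext = ".csv")
  write_bmode(img, ours)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np, pydicom",
    "import pydicom.uid",
    "from pydicom.dataset import Dataset, FileMetaDataset",
    "ds = pydicom.dcmread(sys.argv[1])",
    "arr = ds.pixel_array",
    "np.savetxt(sys.argv[3], arr, fmt='%d', delimiter=',')",
    "fm = FileMetaDataset()",
    "fm.TransferSyntaxUID = pydicom.uid.ExplicitVRLittleEndian",
    "fm.MediaStorageSOPClassUID = pydicom.uid.UltrasoundImageStorage",
    "fm.MediaStorageSOPInstanceUID = pydicom.uid.generate_uid()",
    "out = Dataset(); out.file_meta = fm",
    "out.SOPClassUID = fm.MediaStorageSOPClassUID",
    "out.SOPInstanceUID = fm.MediaStorageSOPInstanceUID",
    "out.Rows, out.Columns = arr.shape",
    "out.SamplesPerPixel = 1",
    "out.PhotometricInterpretation = 'MONOCHROME2'",
    "out.BitsAllocated = out.BitsStored = 8",
    "out.HighBit = 7; out.PixelRepresentation = 0",
    "out.PixelSpacing = [str(ds.PixelSpacing[0]), str(ds.PixelSpacing[1])]",
    "out.PixelData = arr.astype('uint8').tobytes()",
    "out.save_as(sys.argv[2], enforce_file_format=True)"
  ), script)
  status <- system2("python", c(script, ours, theirs, csv_out),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  ref_pixels <- as.matrix(read.csv(csv_out, header = FALSE))
  dimnames(ref_pixels) <- NULL
  expect_equal(ref_pixels, matrix(as.numeric(img$pixels), 16, 16))
  back <- read_bmode(theirs)
  expect_identical(back$pixels, img$pixels)
  expect_equal(back$spacing_y_mm, 0.0176)
})

test_that("color and multi-frame inputs are rejected with a named offense", {
  rgb_path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(0.5, c(4, 4, 3)), rgb_path)
  expect_error(read_bmode(rgb_path), "color")

  multi_path <- withr::local_tempfile(fileext = ".tiff")
  tiff::writeTIFF(list(matrix(0.5, 4, 4), matrix(0.2, 4, 4)), multi_path,
                  bits.per.sample = 8L)
  expect_error(read_bmode(multi_path), "multi-frame")
})

test_that("invalid pixel grids and spacings are rejected", {
  expect_error(bmode_image(matrix(-1L, 2, 2)), "0, 255")
  expect_error(bmode_image(matrix(300L, 2, 2)), "0, 255")
  expect_error(bmode_image(matrix(0L, 2, 2), spacing_x_mm = 0), "positive")
})

test_that("disk rasterization matches the exhaustive distance-check oracle", {
  for (area in c(1, 5, 25, 100, 300)) {
    roi <- circular_roi(50, 50, area)
    expect_equal(nrow(roi$pixels), oracle_disk_count(area), label = paste("area", area))
  }
  expect_true(abs(nrow(circular_roi(0, 0, 100)$pixels) - 100) <= 4)
})

test_that("tiny disks have the expected shapes", {
  expect_equal(as.data.frame(circular_roi(10, 10, 1)$pixels),
               data.frame(row = 10, col = 10))
  plus <- circular_roi(10, 10, 5)$pixels
  expect_equal(nrow(plus), 5L)
  expect_setequal(
    paste(plus$row, plus$col),
    c("10 10", "9 10", "11 10", "10 9", "10 11")
  )
})

test_that("rasterized disks have all eight dihedral symmetries", {
  for (area in c(5, 100, 57)) {
    px <- circular_roi(0, 0, area)$pixels
    key <- function(r, c) sort(paste(r, c))
    base <- key(px$row, px$col)
    expect_identical(key(-px$row, px$col), base)
    expect_identical(key(px$row, -px$col), base)
    expect_identical(key(px$col, px$row), base)
    expect_identical(key(-px$col, -px$row), base)
  }
})

test_that("out-of-bounds ROIs fail on binding with the clipped pixels listed", {
  img <- make_test_image(20, 20, fill = 0)
  expect_error(bind_roi(img, circular_roi(1, 10, 100)), "clipped")
  expect_silent(bind_roi(img, circular_roi(10, 10, 100)))
})

test_that("ROI sidecars round-trip through JSON", {
  roi <- circular_roi(12, 30, 100)
  path <- withr::local_tempfile(fileext = ".json")
  write_roi(roi, path)
  back <- read_roi(path)
  expect_equal(back$pixels, roi$pixels)
  expect_equal(back$nominal_area_px, 100)
})
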