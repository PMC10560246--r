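# DICOM series reading, HU calibration and slice-spacing derivation.

test_that("a phantom series round-trips through the DICOM writer and reader", {
  spec <- box_phantom_spec()
  out <- tempfile("dcm")
  generate_phantom(spec, out)
  series <- read_series(out)
  mem <- phantom_series(spec)
  expect_length(series$slices, 20L)
  expect_equal(series$slice_spacing, 1.0)
  for (k in seq_along(series$slices)) {
    expect_identical(series$slices[[k]]$stored_pixels,
                     mem$slices[[k]]$stored_pixels)
    expect_equal(series$slices[[k]]$image_position,
                 mem$slices[[k]]$image_position)
    expect_equal(series$slices[[k]]$slice_thickness, 1.25)
    expect_equal(series$slices[[k]]$pixel_spacing_row, 1)
  }
  unlink(out, recursive = TRUE)
})

test_that("slice order is by position, not file name", {
  spec <- phantom_spec(rows = 8L, cols = 8L, n_slices = 5L,
                       inserts = list(insert_box(c(4, 4, 2), c(2, 2, 5), -100)))
  series <- phantom_series(spec)
  out <- tempfile("shuffle")
  dir.create(out)
  # write files with names in reverse of spatial order
  for (k in seq_along(series$slices))
    write_dicom_slice(series$slices[[k]],
                      file.path(out, sprintf("file_%02d.dcm", 6L - k)))
  re <- read_series(out)
  z <- vapply(re$slices, function(s) s$image_position[3], numeric(1))
  expect_equal(z, c(0, 1, 2, 3, 4))
  expect_identical(re$slices[[1]]$stored_pixels, series$slices[[1]]$stored_pixels)
  unlink(out, recursive = TRUE)
})

test_that("single-slice series falls back to slice thickness for spacing", {
  spec <- phantom_spec(rows = 8L, cols = 8L, n_slices = 1L,
                       slice_thickness = 1.25,
                       inserts = list(insert_box(c(4, 4, 0), c(2, 2, 2), -100)))
  out <- tempfile("one")
  generate_phantom(spec, out)
  series <- read_series(out)
  expect_length(series$slices, 1L)
  expect_equal(series$slice_spacing, 1.25)
  unlink(out, recursive = TRUE)
})

test_that("mixed-geometry directories and empty directories are rejected", {
  out <- tempfile("mixed")
  dir.create(out)
  expect_error(read_series(out), "no DICOM input")
  sl1 <- new_ct_slice(matrix(0L, 8, 8), 1, -1024, 1, 1, c(0, 0, 0), 1L, 1.25)
  sl2 <- new_ct_slice(matrix(0L, 4, 4), 1, -1024, 1, 1, c(0, 0, 1), 2L, 1.25)
  write_dicom_slice(sl1, file.path(out, "a.dcm"))
  write_dicom_slice(sl2, file.path(out, "b.dcm"))
  expect_error(read_series(out), "mixed series")
  unlink(out, recursive = TRUE)
})

test_that("a file missing a geometry attribute names it as uncalibrated", {
  sl <- new_ct_slice(matrix(0L, 4, 4), 1, -1024, 1, 1, c(0, 0, 0), 1L, 1.25)
  path <- tempfile(fileext = ".dcm")
  write_dicom_slice(sl, path)
  raw <- readBin(path, "raw", file.info(path)$size)
  # excise the RescaleSlope element (0028,1053), DS "1 " -> 10 bytes
  pat <- c(ctsubvol:::.enc_u16(0x0028), ctsubvol:::.enc_u16(0x1053))
  hit <- which(vapply(seq_len(length(raw) - 3L), function(i)
    identical(raw[i:(i + 3L)], pat), logical(1)))
  expect_length(hit, 1L)
  vlen <- ctsubvol:::.u16(raw, hit + 5L)
  stripped <- raw[-(hit:(hit + 7L + vlen))]
  path2 <- tempfile(fileext = ".dcm")
  writeBin(stripped, path2)
  expect_error(read_dicom_slice(path2), "uncalibrated series.*RescaleSlope")
  unlink(c(path, path2))
})

test_that("to_hu applies the affine calibration exactly", {
  mk <- function(stored, slope, intercept)
    new_ct_slice(matrix(as.integer(stored), 1, 1), slope, intercept,
                 1, 1, c(0, 0, 0), 1L, 1)
  expect_equal(to_hu(mk(1024, 1, -1024))[1, 1], 0)      # water
  expect_equal(to_hu(mk(0, 1, -1024))[1, 1], -1024)     # air
  expect_equal(to_hu(mk(462, 2, -1024))[1, 1], -100)
  # affine property over random arrays and calibrations
  set.seed(42)
  for (i in 1:25) {
    stored <- matrix(sample.int(4096L, 30L) - 1L, 5, 6)
    slope <- stats::runif(1, 0.5, 2); intercept <- stats::runif(1, -2000, 0)
    sl <- new_ct_slice(stored, slope, intercept, 1, 1, c(0, 0, 0), 1L, 1)
    expect_equal(to_hu(sl), stored * slope + intercept)
  }
})

test_that("slice spacing is the median gap, warning on irregular stacks", {
  mk_series <- function(zs) {
    slices <- lapply(seq_along(zs), function(k)
      new_ct_slice(matrix(0L, 4, 4), 1, -1024, 1, 1, c(0, 0, zs[k]), k, 1.25))
    new_ct_series(slices)
  }
  expect_equal(mk_series(0:9)$slice_spacing, 1.0)
  expect_equal(mk_series(c(0, 2.5, 5))$slice_spacing, 2.5)
  expect_warning(s <- mk_series(c(0, 1, 2, 4)), "non-uniform slice gaps")
  expect_equal(s$slice_spacing, 1.0)
  expect_error(mk_series(c(0, 0, 1)), "duplicate slice position")
})

test_that("written files conform to DICOM as read by an independent parser", {
  spec <- phantom_spec(rows = 8L, cols = 8L, n_slices = 2L,
                       inserts = list(insert_box(c(4, 4, 0.5), c(4, 4, 2), -100)))
  out <- tempfile("pydcm")
  generate_phantom(spec, out)
  script <- paste(
    "import pydicom, sys",
    "ds = pydicom.dcmread(sys.argv[1])",
    "hu = ds.pixel_array * float(ds.RescaleSlope) + float(ds.RescaleIntercept)",
    "print(ds.Rows, ds.Columns, float(ds.PixelSpacing[0]),",
    "      float(ds.SliceThickness), int(ds.InstanceNumber),",
    "      hu[4, 4], hu[0, 0])",
    sep = "\n")
  res <- suppressWarnings(system2("python", c("-", file.path(out, "slice_0001.dcm")),
                                  input = script, stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  expect_true(is.null(status) || status == 0L)
  fields <- strsplit(tail(res, 1), "\\s+")[[1]]
  expect_equal(as.numeric(fields), c(8, 8, 1, 1.25, 1, -100, 40))
  unlink(out, recursive = TRUE)
})
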