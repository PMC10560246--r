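# Minimal DICOM Part-10 codec for uncompressed single-frame CT.
#
# Scope: Explicit and Implicit VR Little Endian transfer syntaxes,
# MONOCHROME2, 16-bit stored pixels (signed or unsigned). This covers the
# files the phantom writer produces and plain clinical CT exports; compressed
# transfer syntaxes, multi-frame objects and non-CT modalities are rejected.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_CT_IMAGE    <- "1.2.840.10008.5.1.4.1.1.2"
UID_IMPL_CLASS  <- "1.2.826.0.1.3680043.9.7543.1"

# tag helpers: a tag is c(group, element), both integers
.tag_key <- function(group, element) sprintf("%04X,%04X", group, element)

.u16 <- function(raw, offset) {
  as.integer(raw[offset + 1L]) + 256L * as.integer(raw[offset + 2L])
}
.u32 <- function(raw, offset) {
  # doubles avoid integer overflow for lengths near 2^31
  as.numeric(raw[offset + 1L]) + 256 * as.numeric(raw[offset + 2L]) +
    65536 * as.numeric(raw[offset + 3L]) + 16777216 * as.numeric(raw[offset + 4L])
}

.EXPLICIT_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# VRs of the tags this reader interprets (needed for Implicit VR files)
.TAG_VR <- c(
  "0008,0016" = "UI", "0008,0018" = "UI", "0008,0060" = "CS",
  "0018,0050" = "DS", "0018,0088" = "DS",
  "0020,0013" = "IS", "0020,0032" = "DS", "0020,0037" = "DS",
  "0028,0002" = "US", "0028,0004" = "CS",
  "0028,0010" = "US", "0028,0011" = "US", "0028,0030" = "DS",
  "0028,0100" = "US", "0028,0101" = "US", "0028,0102" = "US",
  "0028,0103" = "US",
  "0028,1052" = "DS", "0028,1053" = "DS",
  "7FE0,0010" = "OW"
)

.parse_elements <- function(raw, pos, end, explicit) {
  out <- list()
  while (pos + 8L <= end) {
    group   <- .u16(raw, pos); element <- .u16(raw, pos + 2L)
    key <- .tag_key(group, element)
    if (explicit) {
      vr <- rawToChar(raw[(pos + 5L):(pos + 6L)])
      if (vr %in% .EXPLICIT_LONG_VRS) {
        len <- .u32(raw, pos + 8L); hdr <- 12L
      } else {
        len <- .u16(raw, pos + 6L); hdr <- 8L
      }
    } else {
      vr  <- if (key %in% names(.TAG_VR)) .TAG_VR[[key]] else "UN"
      len <- .u32(raw, pos + 4L); hdr <- 8L
    }
    if (len == 4294967295) {        # undefined length (sequences) — skip not supported
      ct_error(sprintf("unsupported undefined-length element at tag (%s)", key),
               "ct_dicom_error")
    }
    value_start <- pos + hdr
    if (value_start + len > end)
      ct_error("truncated DICOM element stream", "ct_dicom_error")
    if (key %in% names(.TAG_VR) || group == 0x0002L) {
      out[[key]] <- list(vr = vr, raw = raw[seq_len(len) + value_start])
    }
    pos <- value_start + len
  }
  out
}

.element_string <- function(el) {
  if (is.null(el)) return(NULL)
  r <- el$raw
  while (length(r) > 0L && r[length(r)] %in% as.raw(c(0x00, 0x20)))
    r <- r[-length(r)]
  rawToChar(r)
}
.element_numeric <- function(el) {
  s <- .element_string(el)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
.element_us <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$raw, "integer", n = length(el$raw) / 2L, size = 2L,
          signed = FALSE, endian = "little")
}

#' Read one DICOM CT slice
#'
#' Parses a DICOM Part-10 file (Explicit or Implicit VR Little Endian,
#' uncompressed 16-bit monochrome pixel data) into a `ct_slice` object
#' holding the stored pixel matrix and the geometry/calibration attributes
#' needed for Hounsfield-unit volumetry.
#'
#' @param path Path to a DICOM file.
#' @return A `ct_slice`: list with `stored_pixels` (integer matrix,
#'   rows x cols), `rescale_slope`, `rescale_intercept`, `pixel_spacing_row`,
#'   `pixel_spacing_col` (mm), `image_position` (length-3, mm),
#'   `instance_number`, `slice_thickness` (mm).
#' @export
read_dicom_slice <- function(path) {
  n <- file.info(path)$size
  if (is.na(n) || n < 140)
    ct_error(sprintf("not a DICOM file: %s", path), "ct_dicom_error")
  raw <- readBin(path, "raw", n = n)
  if (rawToChar(raw[129:132]) != "DICM")
    ct_error(sprintf("not a DICOM Part-10 file (missing DICM magic): %s", path),
             "ct_dicom_error")
  pos <- 132L
  # file meta group is always Explicit VR LE; (0002,0000) gives its length
  if (.u16(raw, pos) != 0x0002L || .u16(raw, pos + 2L) != 0x0000L)
    ct_error(sprintf("missing file meta group length: %s", path), "ct_dicom_error")
  meta_len <- .u32(raw, pos + 8L)
  meta_end <- pos + 12L + meta_len
  meta <- .parse_elements(raw, pos + 12L, meta_end, explicit = TRUE)
  ts <- .element_string(meta[["0002,0010"]])
  if (is.null(ts))
    ct_error(sprintf("missing TransferSyntaxUID: %s", path), "ct_dicom_error")
  if (!ts %in% c(UID_EXPLICIT_LE, UID_IMPLICIT_LE))
    ct_error(sprintf("unsupported transfer syntax %s: %s", ts, path),
             "ct_dicom_error")
  els <- .parse_elements(raw, meta_end, n, explicit = ts == UID_EXPLICIT_LE)

  need <- function(key, name, fn) {
    v <- fn(els[[key]])
    if (is.null(v) || length(v) == 0L)
      ct_error(sprintf("uncalibrated series: missing %s in %s", name, path),
               "ct_uncalibrated_error")
    v
  }
  rows <- need("0028,0010", "Rows", .element_us)
  cols <- need("0028,0011", "Columns", .element_us)
  spacing   <- need("0028,0030", "PixelSpacing", .element_numeric)
  slope     <- need("0028,1053", "RescaleSlope", .element_numeric)
  intercept <- need("0028,1052", "RescaleIntercept", .element_numeric)
  ipp       <- need("0020,0032", "ImagePositionPatient", .element_numeric)
  inst      <- need("0020,0013", "InstanceNumber", .element_numeric)
  thickness <- need("0018,0050", "SliceThickness", .element_numeric)
  bits_alloc <- .element_us(els[["0028,0100"]])
  pixel_rep  <- .element_us(els[["0028,0103"]])
  if (is.null(bits_alloc)) bits_alloc <- 16L
  if (is.null(pixel_rep)) pixel_rep <- 0L
  if (bits_alloc != 16L)
    ct_error(sprintf("unsupported BitsAllocated %d: %s", bits_alloc, path),
             "ct_dicom_error")
  px <- els[["7FE0,0010"]]
  if (is.null(px))
    ct_error(sprintf("uncalibrated series: missing PixelData in %s", path),
             "ct_uncalibrated_error")
  npix <- rows * cols
  if (length(px$raw) < 2L * npix)
    ct_error(sprintf("PixelData shorter than Rows x Columns: %s", path),
             "ct_dicom_error")
  stored <- readBin(px$raw, "integer", n = npix, size = 2L,
                    signed = pixel_rep == 1L, endian = "little")
  # DICOM pixel order is row-major (first row first)
  mat <- matrix(stored, nrow = rows, ncol = cols, byrow = TRUE)
  new_ct_slice(
    stored_pixels = mat,
    rescale_slope = slope[1], rescale_intercept = intercept[1],
    pixel_spacing_row = spacing[1], pixel_spacing_col = spacing[2],
    image_position = ipp[1:3], instance_number = as.integer(inst[1]),
    slice_thickness = thickness[1]
  )
}

#' Construct a CT slice object
#'
#' @param stored_pixels Integer matrix of stored pixel values (rows x cols).
#' @param rescale_slope,rescale_intercept Affine HU calibration: HU =
#'   stored * slope + intercept.
#' @param pixel_spacing_row,pixel_spacing_col In-plane pixel spacing in mm.
#' @param image_position Length-3 position (mm) of the first voxel in patient
#'   coordinates.
#' @param instance_number Integer acquisition index.
#' @param slice_thickness Reconstructed slice thickness in mm.
#' @return A `ct_slice` object.
#' @export
new_ct_slice <- function(stored_pixels, rescale_slope, rescale_intercept,
                         pixel_spacing_row, pixel_spacing_col,
                         image_position, instance_number, slice_thickness) {
  stopifnot(is.matrix(stored_pixels), nrow(stored_pixels) >= 1L,
            ncol(stored_pixels) >= 1L,
            pixel_spacing_row > 0, pixel_spacing_col > 0,
            slice_thickness > 0, length(image_position) == 3L)
  structure(list(
    stored_pixels = stored_pixels,
    rescale_slope = as.numeric(rescale_slope),
    rescale_intercept = as.numeric(rescale_intercept),
    pixel_spacing_row = as.numeric(pixel_spacing_row),
    pixel_spacing_col = as.numeric(pixel_spacing_col),
    image_position = as.numeric(image_position),
    instance_number = as.integer(instance_number),
    slice_thickness = as.numeric(slice_thickness)
  ), class = "ct_slice")
}

#' Convert a slice's stored pixels to Hounsfield units
#'
#' Applies the standard DICOM affine calibration
#' `HU = stored * RescaleSlope + RescaleIntercept`, elementwise, with no
#' clipping or rounding (thresholding must be exact at interval endpoints).
#'
#' @param slice A `ct_slice`.
#' @return Numeric matrix of HU values, same shape as the stored pixels.
#' @export
to_hu <- function(slice) {
  stopifnot(inherits(slice, "ct_slice"))
  slice$stored_pixels * slice$rescale_slope + slice$rescale_intercept
}

#' Read a DICOM CT series directory
#'
#' Reads every file in `directory_path` as a DICOM slice, checks in-plane
#' geometry consistency, sorts slices by position along the dominant stack
#' axis (ties broken by InstanceNumber), and derives the slice spacing
#' (reconstruction increment) from consecutive positions.
#'
#' @param directory_path Directory containing one DICOM file per axial slice.
#' @return A `ct_series`: list with `slices` (list of `ct_slice`, sorted) and
#'   `slice_spacing` (mm, center-to-center).
#' @export
read_series <- function(directory_path) {
  files <- list.files(directory_path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  # keep Part-10 files (DICM magic); sidecar files (ROI CSV, JSON) are legal
  is_dicom <- vapply(files, function(f) {
    n <- file.info(f)$size
    if (is.na(n) || n < 132) return(FALSE)
    con <- file(f, "rb"); on.exit(close(con))
    hdr <- readBin(con, "raw", n = 132)
    identical(rawToChar(hdr[129:132]), "DICM")
  }, logical(1))
  if (!any(is_dicom))
    ct_error(sprintf("no DICOM input in %s", directory_path), "ct_no_input_error")
  slices <- lapply(files[is_dicom], read_dicom_slice)
  new_ct_series(slices)
}

#' Assemble slices into an ordered CT series
#'
#' @param slices List of `ct_slice` objects (any order).
#' @return A sorted `ct_series` with derived `slice_spacing`.
#' @export
new_ct_series <- function(slices) {
  if (length(slices) == 0L) ct_error("no DICOM input", "ct_no_input_error")
  dims <- vapply(slices, function(s) dim(s$stored_pixels), integer(2))
  sp <- vapply(slices, function(s) c(s$pixel_spacing_row, s$pixel_spacing_col),
               numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]) ||
      any(abs(sp - sp[, 1]) > 1e-9))
    ct_error("mixed series: slices differ in dimensions or pixel spacing",
             "ct_mixed_series_error")
  pos <- t(vapply(slices, function(s) s$image_position, numeric(3)))
  # stack axis = patient axis with the largest positional variance
  axis <- if (nrow(pos) > 1L) which.max(apply(pos, 2, stats::var)) else 3L
  inst <- vapply(slices, function(s) s$instance_number, integer(1))
  ord <- order(pos[, axis], inst)
  slices <- slices[ord]
  series <- structure(list(slices = slices, slice_spacing = NA_real_,
                           stack_axis = axis),
                      class = "ct_series")
  series$slice_spacing <- compute_slice_spacing(series)
  series
}

#' Derive slice spacing from slice positions
#'
#' Returns the median absolute center-to-center distance between consecutive
#' slices projected on the stack axis (the reconstruction increment). A
#' single-slice series falls back to the slice thickness. A non-fatal warning
#' is raised if any gap deviates from the median by more than 1%.
#'
#' @param series A sorted `ct_series`.
#' @return Slice spacing in mm.
#' @export
compute_slice_spacing <- function(series) {
  stopifnot(inherits(series, "ct_series"))
  if (length(series$slices) == 1L) return(series$slices[[1]]$slice_thickness)
  axis <- series$stack_axis
  z <- vapply(series$slices, function(s) s$image_position[axis], numeric(1))
  gaps <- abs(diff(z))
  if (any(gaps == 0))
    ct_error("duplicate slice position in series", "ct_duplicate_position_error")
  med <- stats::median(gaps)
  if (any(abs(gaps - med) > 0.01 * med))
    ct_warn(sprintf(
      "non-uniform slice gaps: median %.4g mm, range [%.4g, %.4g] mm",
      med, min(gaps), max(gaps)), "ct_gap_warning")
  med
}

#' @export
print.ct_series <- function(x, ...) {
  s1 <- x$slices[[1]]
  cat(sprintf(
    "CT series: %d slice(s), %d x %d px, pixel spacing %.4g x %.4g mm,\n  slice spacing %.4g mm, slice thickness %.4g mm\n",
    length(x$slices), nrow(s1$stored_pixels), ncol(s1$stored_pixels),
    s1$pixel_spacing_row, s1$pixel_spacing_col,
    x$slice_spacing, s1$slice_thickness))
  invisible(x)
}

# ---- writer ------------------------------------------------------------

.enc_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.enc_u32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

.enc_element <- function(group, element, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  hdr <- c(.enc_u16(group), .enc_u16(element), charToRaw(vr))
  if (vr %in% .EXPLICIT_LONG_VRS) {
    c(hdr, as.raw(c(0, 0)), .enc_u32(length(value_raw)), value_raw)
  } else {
    c(hdr, .enc_u16(length(value_raw)), value_raw)
  }
}

.enc_str <- function(group, element, vr, s) .enc_element(group, element, vr, charToRaw(s))
.enc_us  <- function(group, element, x)
  .enc_element(group, element, "US", writeBin(as.integer(x), raw(), size = 2L, endian = "little"))
.enc_ds  <- function(group, element, x)
  .enc_str(group, element, "DS", paste(formatC(x, format = "fg", digits = 10), collapse = "\\"))

#' Write one CT slice as a DICOM Part-10 file
#'
#' Emits an uncompressed Explicit VR Little Endian CT Image Storage file with
#' signed 16-bit pixels and the attributes [read_dicom_slice()] requires.
#'
#' @param slice A `ct_slice`.
#' @param path Output file path.
#' @param sop_instance_uid Optional SOP Instance UID; a deterministic UID
#'   derived from the instance number is used by default.
#' @return `path`, invisibly.
#' @export
write_dicom_slice <- function(slice, path,
                              sop_instance_uid = paste0(UID_IMPL_CLASS, ".",
                                                        slice$instance_number)) {
  stopifnot(inherits(slice, "ct_slice"))
  stored <- slice$stored_pixels
  if (any(stored < -32768L | stored > 32767L))
    ct_error("stored pixel value outside signed 16-bit range", "ct_range_error")
  # row-major pixel stream
  pix_raw <- writeBin(as.integer(t(stored)), raw(), size = 2L, endian = "little")

  meta_body <- c(
    .enc_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .enc_str(0x0002, 0x0002, "UI", UID_CT_IMAGE),
    .enc_str(0x0002, 0x0003, "UI", sop_instance_uid),
    .enc_str(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    .enc_str(0x0002, 0x0012, "UI", UID_IMPL_CLASS)
  )
  meta <- c(.enc_element(0x0002, 0x0000, "UL", .enc_u32(length(meta_body))),
            meta_body)
  body <- c(
    .enc_str(0x0008, 0x0016, "UI", UID_CT_IMAGE),
    .enc_str(0x0008, 0x0018, "UI", sop_instance_uid),
    .enc_str(0x0008, 0x0060, "CS", "CT"),
    .enc_ds(0x0018, 0x0050, slice$slice_thickness),
    .enc_str(0x0020, 0x0013, "IS", as.character(slice$instance_number)),
    .enc_ds(0x0020, 0x0032, slice$image_position),
    .enc_ds(0x0020, 0x0037, c(1, 0, 0, 0, 1, 0)),
    .enc_us(0x0028, 0x0002, 1L),
    .enc_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .enc_us(0x0028, 0x0010, nrow(stored)),
    .enc_us(0x0028, 0x0011, ncol(stored)),
    .enc_ds(0x0028, 0x0030, c(slice$pixel_spacing_row, slice$pixel_spacing_col)),
    .enc_us(0x0028, 0x0100, 16L),
    .enc_us(0x0028, 0x0101, 16L),
    .enc_us(0x0028, 0x0102, 15L),
    .enc_us(0x0028, 0x0103, 1L),
    .enc_ds(0x0028, 0x1052, slice$rescale_intercept),
    .enc_ds(0x0028, 0x1053, slice$rescale_slope),
    .enc_element(0x7FE0, 0x0010, "OW", pix_raw)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}
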