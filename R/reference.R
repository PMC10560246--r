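# Independent brute-force quantifier used as an oracle in equivalence tests.
#
# Deliberately shares no code with the scanline rasterizer or quantify():
# point-in-polygon is re-derived per pixel with an explicit edge loop
# (pnpoly-style even-odd crossing count), thresholding and the volume
# arithmetic are re-stated inline. Slow by design; use small grids.

# even-odd test of a single perturbed point against one polygon
.pip_even_odd <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py)) {
      x_cross <- xs[i] + (py - ys[i]) * (xs[j] - xs[i]) / (ys[j] - ys[i])
      if (px < x_cross) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Brute-force reference quantification (oracle)
#'
#' Recomputes the [quantify()] result by looping over every pixel of every
#' slice and testing its perturbed center (+2^-20 px on both axes)
#' independently against each polygon. Intended for equivalence testing on
#' small grids, not for production use.
#'
#' @inheritParams quantify
#' @return A `volume_report` with the same fields as [quantify()].
#' @export
reference_quantify <- function(series, roiset, range = hu_range(),
                               depth_mode = c("increment", "thickness")) {
  stopifnot(inherits(series, "ct_series"), inherits(roiset, "roi_set"),
            inherits(range, "hu_range"))
  depth_mode <- match.arg(depth_mode)
  n_slices <- length(series$slices)
  if (roiset$n_slices != n_slices)
    ct_error("ROI/series mismatch", "ct_roi_mismatch_error")
  if (sum(lengths(roiset$polygons)) == 0L)
    ct_error("empty region: ROI set contains no polygons", "ct_empty_roi_error")
  s1 <- series$slices[[1]]
  rows <- nrow(s1$stored_pixels); cols <- ncol(s1$stored_pixels)
  depth <- if (depth_mode == "increment") series$slice_spacing
           else s1$slice_thickness
  eps <- 2^-20
  n_roi <- integer(n_slices); n_sub <- integer(n_slices)
  for (k in seq_len(n_slices)) {
    polys <- roiset$polygons[[k]]
    if (length(polys) == 0L) next
    sl <- series$slices[[k]]
    hu <- sl$stored_pixels * sl$rescale_slope + sl$rescale_intercept
    for (i in seq_len(rows)) {
      py <- (i - 1L) + eps
      for (j in seq_len(cols)) {
        px <- (j - 1L) + eps
        in_roi <- FALSE
        for (p in polys) {
          if (.pip_even_odd(px, py, p$x, p$y)) { in_roi <- TRUE; break }
        }
        if (in_roi) {
          n_roi[k] <- n_roi[k] + 1L
          v <- hu[i, j]
          if (v >= range$lo && v <= range$hi) n_sub[k] <- n_sub[k] + 1L
        }
      }
    }
  }
  voxel_mm3 <- s1$pixel_spacing_row * s1$pixel_spacing_col * depth
  total_cm3 <- sum(n_roi) * voxel_mm3 / 1000
  sub_cm3 <- sum(n_sub) * voxel_mm3 / 1000
  structure(list(
    n_roi_voxels = sum(n_roi), n_sub_voxels = sum(n_sub),
    total_volume_cm3 = total_cm3, sub_volume_cm3 = sub_cm3,
    sub_percentage = if (total_cm3 > 0) 100 * sub_cm3 / total_cm3 else 0,
    hu_range = range, depth_mode = depth_mode, voxel_volume_mm3 = voxel_mm3,
    per_slice = data.frame(slice_index = seq_len(n_slices) - 1L,
                           n_roi = n_roi, n_sub = n_sub)
  ), class = "volume_report")
}
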