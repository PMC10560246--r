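# Scanline polygon rasterization under the even-odd rule.
#
# A pixel belongs to the mask iff its center satisfies the even-odd
# (ray-crossing parity) rule against the closed polygon. Centers that lie
# exactly on an edge are resolved deterministically by perturbing the test
# point by (+eps, +eps) with eps = 2^-20 px, so no crossing ever happens at
# a vertex or along a horizontal edge. Parts of the polygon outside the grid
# are clipped (with a warning): off-grid pixels cannot be counted.

.RASTER_EPS <- 2^-20

#' Rasterize a polygon to a pixel mask
#'
#' @param polygon A [polygon2d()] in pixel coordinates (integer coordinate =
#'   pixel center, origin at the top-left pixel center).
#' @param rows,cols Grid dimensions.
#' @return Logical matrix `rows x cols`; `[i, j]` is the pixel with center
#'   (x = j - 1, y = i - 1).
#' @export
rasterize_polygon <- function(polygon, rows, cols) {
  stopifnot(inherits(polygon, "polygon2d"), rows >= 1L, cols >= 1L)
  xs <- polygon$x; ys <- polygon$y
  if (min(xs) < -0.5 || max(xs) > cols - 0.5 ||
      min(ys) < -0.5 || max(ys) > rows - 0.5)
    ct_warn("polygon extends beyond the pixel grid; clipping", "ct_clip_warning")
  mask <- matrix(FALSE, rows, cols)
  n <- length(xs)
  x2 <- xs[c(2:n, 1)]; y2 <- ys[c(2:n, 1)]
  eps <- .RASTER_EPS
  r_lo <- max(0L, ceiling(min(ys) - eps))
  r_hi <- min(rows - 1L, floor(max(ys)))
  if (r_hi < r_lo) return(mask)
  xc <- (seq_len(cols) - 1L) + eps           # perturbed test abscissae
  for (r in r_lo:r_hi) {
    yt <- r + eps                            # perturbed scanline ordinate
    crosses <- (ys > yt) != (y2 > yt)
    if (!any(crosses)) next
    xi <- xs[crosses] + (yt - ys[crosses]) *
      (x2[crosses] - xs[crosses]) / (y2[crosses] - ys[crosses])
    # center inside iff an odd number of crossings lie strictly left of it
    parity <- findInterval(xc, sort(xi)) %% 2L == 1L
    mask[r + 1L, ] <- parity
  }
  mask
}

#' Inclusive Hounsfield-unit interval
#'
#' @param lo,hi Interval endpoints in HU, `lo <= hi`; both endpoints are
#'   included when thresholding. Defaults to the adipose attenuation range
#'   -150 to -50 HU. Infinite endpoints are allowed, so the complement of a
#'   range can be expressed as two half-open rays.
#' @return An `hu_range` object.
#' @export
hu_range <- function(lo = -150, hi = -50) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (is.na(lo) || is.na(hi) || lo > hi)
    ct_error("invalid HU range: need lo <= hi", "ct_usage_error")
  structure(list(lo = lo, hi = hi), class = "hu_range")
}

#' Threshold an HU image to a mask
#'
#' @param hu Numeric matrix of Hounsfield units (see [to_hu()]).
#' @param range An [hu_range()]; both endpoints inclusive.
#' @return Logical matrix: `lo <= hu <= hi`.
#' @export
threshold_mask <- function(hu, range = hu_range()) {
  stopifnot(inherits(range, "hu_range"))
  hu >= range$lo & hu <= range$hi
}
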