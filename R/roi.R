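# Per-slice polygon regions of interest.
#
# Coordinate convention (pixel coordinates of one slice): x runs along
# columns, y along rows; integer coordinate = pixel center; origin at the
# center of the top-left pixel. Polygons are implicitly closed last -> first.
#
# CSV dialect (stands in for the interactive workstation export after a
# pre-conversion step): header `slice_index,roi_id,vertex_index,x_px,y_px`,
# UTF-8, comma-separated, decimal point, no quoting. slice_index is the
# 0-based position of the slice in the sorted series.

#' Construct a 2-D polygon in pixel coordinates
#'
#' @param x,y Numeric vertex coordinates (pixels; x along columns, y along
#'   rows). At least 3 vertices; the closing edge last -> first is implicit.
#' @return A `polygon2d` object (list with `x`, `y`).
#' @export
polygon2d <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L)
    ct_error("degenerate polygon: fewer than 3 vertices", "ct_roi_error")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    ct_error("polygon with non-finite coordinates", "ct_roi_error")
  if (any(diff(x) == 0 & diff(y) == 0))
    ct_error("polygon with repeated consecutive vertices", "ct_roi_error")
  structure(list(x = x, y = y), class = "polygon2d")
}

#' Construct a per-slice ROI set
#'
#' @param polygons Named or index-addressed list: `polygons[[k]]` is the list
#'   of `polygon2d` for slice index `k - 1` (0-based slice addressing, as in
#'   the CSV dialect). Entries may be empty lists.
#' @param n_slices Number of slices in the target series.
#' @return An `roi_set` object.
#' @export
roi_set <- function(polygons, n_slices) {
  n_slices <- as.integer(n_slices)
  stopifnot(n_slices >= 1L)
  if (length(polygons) > n_slices)
    ct_error("ROI/series mismatch: more ROI slices than series slices",
             "ct_roi_mismatch_error")
  out <- vector("list", n_slices)
  for (k in seq_len(n_slices)) {
    out[[k]] <- if (k <= length(polygons) && !is.null(polygons[[k]]))
      polygons[[k]] else list()
    ok <- vapply(out[[k]], inherits, logical(1), what = "polygon2d")
    if (length(ok) && !all(ok))
      ct_error("roi_set entries must be polygon2d objects", "ct_roi_error")
  }
  structure(list(polygons = out, n_slices = n_slices), class = "roi_set")
}

#' Read a per-slice polygon ROI file
#'
#' Parses the documented CSV dialect (header
#' `slice_index,roi_id,vertex_index,x_px,y_px`) into an [roi_set()],
#' validating slice indices against the series.
#'
#' @param path CSV file path.
#' @param series The `ct_series` the ROIs apply to.
#' @return An `roi_set` with one (possibly empty) polygon list per slice.
#' @export
read_roi_csv <- function(path, series) {
  stopifnot(inherits(series, "ct_series"))
  if (!file.exists(path))
    ct_error(sprintf("ROI file not found: %s", path), "ct_roi_error")
  lines <- readLines(path)
  if (length(lines) < 1L ||
      gsub("\\s", "", lines[1]) != "slice_index,roi_id,vertex_index,x_px,y_px")
    ct_error("malformed ROI file: missing or wrong header", "ct_roi_error")
  n_slices <- length(series$slices)
  if (length(lines) == 1L) return(roi_set(list(), n_slices))
  df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                        strip.white = TRUE)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L)
      ct_error(sprintf("malformed ROI file: non-numeric %s at data row %d",
                       col, bad[1]), "ct_roi_error")
    v
  }
  si <- num("slice_index"); ri <- num("roi_id"); vi <- num("vertex_index")
  x <- num("x_px"); y <- num("y_px")
  if (any(si < 0 | si >= n_slices | si != floor(si)))
    ct_error(sprintf(
      "ROI/series mismatch: slice_index outside [0, %d)", n_slices),
      "ct_roi_mismatch_error")
  polys <- vector("list", n_slices)
  for (k in seq_len(n_slices)) polys[[k]] <- list()
  for (grp in split(seq_along(si), list(si, ri), drop = TRUE)) {
    ord <- grp[order(vi[grp])]
    if (length(ord) < 3L)
      ct_error(sprintf("degenerate polygon: roi_id %g on slice %g has %d vertices",
                       ri[grp[1]], si[grp[1]], length(ord)), "ct_roi_error")
    k <- si[ord[1]] + 1L
    polys[[k]] <- c(polys[[k]], list(polygon2d(x[ord], y[ord])))
  }
  roi_set(polys, n_slices)
}

#' Write a per-slice polygon ROI file
#'
#' Writes the same CSV dialect [read_roi_csv()] parses, with deterministic
#' row order (slice, roi, vertex ascending).
#'
#' @param roiset An `roi_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roi_csv <- function(roiset, path) {
  stopifnot(inherits(roiset, "roi_set"))
  rows <- list("slice_index,roi_id,vertex_index,x_px,y_px")
  for (k in seq_along(roiset$polygons)) {
    pl <- roiset$polygons[[k]]
    for (r in seq_along(pl)) {
      p <- pl[[r]]
      rows[[length(rows) + 1L]] <- paste(sprintf(
        "%d,%d,%d,%.17g,%.17g", k - 1L, r, seq_along(p$x) - 1L, p$x, p$y),
        collapse = "\n")
    }
  }
  writeLines(unlist(rows), path)
  invisible(path)
}

#' @export
print.roi_set <- function(x, ...) {
  n_poly <- sum(lengths(x$polygons))
  cat(sprintf("ROI set: %d polygon(s) over %d slice(s) (%d slice(s) outlined)\n",
              n_poly, x$n_slices, sum(lengths(x$polygons) > 0L)))
  invisible(x)
}
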