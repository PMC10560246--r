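# Shared fixtures, built in code at test time.

# voxel-aligned 10 x 10 x 20 mm box at -100 HU on a 1 mm isotropic grid;
# the box occupies pixel centers x,y in 5..14 and all 20 slices
box_phantom_spec <- function(noise_sd = 0, seed = 1L, roi = NULL,
                             background_hu = 40) {
  phantom_spec(rows = 32L, cols = 32L, pixel_spacing = 1, n_slices = 20L,
               slice_spacing = 1, slice_thickness = 1.25,
               background_hu = background_hu,
               inserts = list(insert_box(c(10, 10, 9.5), c(10, 10, 20), -100)),
               roi = roi, seed = seed, noise_sd = noise_sd)
}

# ROI square whose pixel-center raster is exactly the box footprint
tight_box_roi <- function() polygon2d(c(4.5, 14.5, 14.5, 4.5),
                                      c(4.5, 4.5, 14.5, 14.5))

random_polygon <- function(rows, cols, n_min = 3L, n_max = 12L) {
  repeat {
    n <- sample(n_min:n_max, 1L)
    x <- stats::runif(n, -1, cols)
    y <- stats::runif(n, -1, rows)
    if (!any(diff(x) == 0 & diff(y) == 0)) return(polygon2d(x, y))
  }
}

# test-local brute-force rasterization oracle: even-odd ray cast of every
# pixel center independently (kept separate from both the package's scanline
# rasterizer and its reference_quantify() oracle)
raycast_mask <- function(poly, rows, cols) {
  eps <- 2^-20
  xs <- poly$x; ys <- poly$y
  n <- length(xs)
  xn <- xs[c(2:n, 1)]; yn <- ys[c(2:n, 1)]
  mask <- matrix(FALSE, rows, cols)
  for (i in seq_len(rows)) {
    py <- (i - 1) + eps
    for (j in seq_len(cols)) {
      px <- (j - 1) + eps
      crosses <- (ys > py) != (yn > py)
      if (any(crosses)) {
        xc <- xs[crosses] + (py - ys[crosses]) *
          (xn[crosses] - xs[crosses]) / (yn[crosses] - ys[crosses])
        mask[i, j] <- sum(xc > px) %% 2 == 1
      }
    }
  }
  mask
}

# small random phantom (box or cylinder insert, random ROI polygon) for
# core-vs-oracle equivalence runs
random_phantom <- function() {
  rows <- sample(16:28, 1L); cols <- sample(16:28, 1L)
  ps <- sample(c(0.5, 1, 2), 1L)
  n_slices <- sample(3:6, 1L)
  hu <- sample(c(-100, -150, -50, -60, 40), 1L)
  w <- cols * ps; h <- rows * ps
  ins <- if (stats::runif(1) < 0.5) {
    insert_box(c(w / 2, h / 2, 1), c(w / 3, h / 3, 2.5), hu)
  } else {
    insert_cylinder(c(w / 2, h / 2, 1), min(w, h) / 4, 2.5, hu)
  }
  spec <- phantom_spec(rows = rows, cols = cols, pixel_spacing = ps,
                       n_slices = n_slices, slice_spacing = 1,
                       inserts = list(ins),
                       roi = random_polygon(rows, cols),
                       noise_sd = sample(c(0, 5), 1L),
                       seed = sample.int(1e6, 1L))
  list(series = phantom_series(spec), roi = phantom_roi(spec), spec = spec)
}
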