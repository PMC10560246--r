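# Rasterization, thresholding and volume conversion.

test_that("a pixel-center-aligned square rasterizes to exactly its interior", {
  m <- rasterize_polygon(polygon2d(c(0.5, 2.5, 2.5, 0.5),
                                   c(0.5, 0.5, 2.5, 2.5)), 5, 5)
  expect_equal(sum(m), 4L)
  expect_true(all(m[2:3, 2:3]))
})

test_that("degenerate polygons rasterize to empty masks", {
  m <- rasterize_polygon(polygon2d(c(0, 1, 2), c(0, 1, 2)), 8, 8)
  expect_equal(sum(m), 0L)
})

test_that("polygons beyond the grid are clipped with a warning", {
  expect_warning(
    m <- rasterize_polygon(polygon2d(c(-3.5, 3.5, 3.5, -3.5),
                                     c(-3.5, -3.5, 3.5, 3.5)), 6, 6),
    "clipping")
  expect_equal(sum(m), 16L)   # centers 0..3 in both axes
})

test_that("scanline rasterization matches a per-pixel ray-cast oracle", {
  set.seed(2024)
  for (rep in 1:60) {
    p <- random_polygon(24, 24)
    fast <- suppressWarnings(rasterize_polygon(p, 24, 24))
    slow <- raycast_mask(p, 24, 24)
    expect_identical(fast, slow)
  }
})

test_that("thresholding is inclusive at both interval endpoints", {
  hu <- matrix(c(-150, -50, -150.5, -49.9, -100, 40), 2, 3)
  m <- threshold_mask(hu, hu_range(-150, -50))
  expect_equal(as.vector(m), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  set.seed(5)
  f <- matrix(stats::runif(400, -300, 100), 20, 20)
  r <- hu_range(-180, -70)
  expect_identical(threshold_mask(f, r), f >= -180 & f <= -70)
})

test_that("the voxel-aligned box phantom is recovered exactly", {
  spec <- box_phantom_spec(roi = tight_box_roi())
  rep <- quantify(phantom_series(spec), phantom_roi(spec))
  expect_equal(rep$total_volume_cm3, 2.000)
  expect_equal(rep$sub_volume_cm3, 2.000)
  expect_equal(rep$sub_percentage, 100)
  expect_equal(rep$n_sub_voxels, 2000L)
})

test_that("a soft-tissue-only region yields zero sub-volume", {
  spec <- phantom_spec(rows = 32L, cols = 32L, n_slices = 20L,
                       inserts = list(insert_box(c(10, 10, 9.5),
                                                 c(10, 10, 20), 40)),
                       roi = tight_box_roi())
  rep <- quantify(phantom_series(spec), phantom_roi(spec))
  expect_equal(rep$sub_volume_cm3, 0)
  expect_equal(rep$sub_percentage, 0)
})

test_that("an ROI set with no polygons is an error, not a zero report", {
  spec <- box_phantom_spec()
  series <- phantom_series(spec)
  empty <- roi_set(list(), length(series$slices))
  expect_error(quantify(series, empty), "empty region")
})

test_that("fat_percentage follows its contract", {
  expect_equal(fat_percentage(2.0, 10.0), 20.0)
  expect_equal(fat_percentage(0, 10.0), 0)
  expect_equal(fat_percentage(3.7, 3.7), 100)
  expect_warning(p <- fat_percentage(0, 0), "empty region")
  expect_equal(p, 0)
  expect_error(fat_percentage(2, 1), "sub <= total")
})

test_that("sub-volumes partition the total over a range and its complement", {
  set.seed(77)
  for (rep in 1:10) {
    ph <- random_phantom()
    lo <- stats::runif(1, -200, -80); hi <- lo + stats::runif(1, 10, 120)
    q_in <- suppressWarnings(quantify(ph$series, ph$roi, hu_range(lo, hi)))
    q_below <- suppressWarnings(
      quantify(ph$series, ph$roi, hu_range(-Inf, lo - 1e-9)))
    q_above <- suppressWarnings(
      quantify(ph$series, ph$roi, hu_range(hi + 1e-9, Inf)))
    expect_identical(q_in$n_sub_voxels + q_below$n_sub_voxels +
                       q_above$n_sub_voxels, q_in$n_roi_voxels)
    expect_equal(q_in$sub_volume_cm3 + q_below$sub_volume_cm3 +
                   q_above$sub_volume_cm3, q_in$total_volume_cm3)
  }
})

test_that("widening the HU range never decreases the sub-voxel count", {
  set.seed(88)
  ph <- suppressWarnings(random_phantom())
  for (rep in 1:15) {
    lo <- stats::runif(1, -250, -60); hi <- lo + stats::runif(1, 5, 100)
    pad <- stats::runif(2, 0, 60)
    inner <- suppressWarnings(quantify(ph$series, ph$roi, hu_range(lo, hi)))
    outer <- suppressWarnings(
      quantify(ph$series, ph$roi, hu_range(lo - pad[1], hi + pad[2])))
    expect_gte(outer$n_sub_voxels, inner$n_sub_voxels)
  }
})

test_that("volumes scale exactly with pixel and slice spacing", {
  base <- phantom_spec(rows = 24L, cols = 24L, pixel_spacing = 1,
                       n_slices = 6L, slice_spacing = 1,
                       inserts = list(insert_box(c(8, 8, 2), c(6, 6, 4), -100)),
                       roi = polygon2d(c(1.2, 20.7, 18.3), c(1.8, 2.1, 21.4)))
  double_px <- phantom_spec(rows = 24L, cols = 24L, pixel_spacing = 2,
                            n_slices = 6L, slice_spacing = 1,
                            inserts = list(insert_box(c(16, 16, 2),
                                                      c(12, 12, 4), -100)),
                            roi = base$roi)
  double_z <- phantom_spec(rows = 24L, cols = 24L, pixel_spacing = 1,
                           n_slices = 6L, slice_spacing = 2,
                           inserts = list(insert_box(c(8, 8, 4), c(6, 6, 8), -100)),
                           roi = base$roi)
  q0 <- quantify(phantom_series(base), phantom_roi(base))
  q1 <- quantify(phantom_series(double_px), phantom_roi(double_px))
  q2 <- quantify(phantom_series(double_z), phantom_roi(double_z))
  expect_identical(q1$n_roi_voxels, q0$n_roi_voxels)  # same stored grid + px polygon
  expect_equal(q1$total_volume_cm3, 4 * q0$total_volume_cm3)
  expect_equal(q1$sub_volume_cm3, 4 * q0$sub_volume_cm3)
  expect_equal(q2$total_volume_cm3, 2 * q0$total_volume_cm3)
  expect_equal(q2$sub_volume_cm3, 2 * q0$sub_volume_cm3)
})

test_that("depth mode switches between increment and thickness exactly", {
  spec <- box_phantom_spec(roi = tight_box_roi())
  series <- phantom_series(spec); roi <- phantom_roi(spec)
  inc <- quantify(series, roi, depth_mode = "increment")
  thk <- quantify(series, roi, depth_mode = "thickness")
  expect_identical(thk$n_sub_voxels, inc$n_sub_voxels)
  expect_equal(thk$total_volume_cm3, 1.25 * inc$total_volume_cm3)
  expect_equal(thk$sub_volume_cm3, 1.25 * inc$sub_volume_cm3)
})
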