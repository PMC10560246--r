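---
title: "Hounsfield-unit sub-volume quantification: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hounsfield-unit sub-volume quantification: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctsubvol)
```

## The measurement model

CT expresses attenuation on the Hounsfield scale (water 0 HU, air −1000 HU),
calibrated per slice by the DICOM affine transform
`HU = stored * RescaleSlope + RescaleIntercept`. Because tissue classes
occupy characteristic HU bands, the volume of a tissue inside an outlined
anatomical compartment can be estimated by counting voxels: a voxel belongs
to the compartment if its center lies inside the slice's ROI polygons, and
to the target tissue if additionally its HU lies in a closed interval
`[lo, hi]` — by default −150 to −50 HU, the conventional adipose band.
Counts convert to volumes through the voxel volume
`pixel_spacing_row * pixel_spacing_col * depth`, and the tissue fraction is
`100 * V_sub / V_total`.

Three modelling decisions deserve emphasis:

* **Closed interval at both ends.** "−150 to −50 HU" is read symmetrically;
  −150 and −50 are counted, −150.5 and −49.9 are not. HU values are kept as
  floats after rescaling (no rounding), so endpoint behavior is exact.
* **Binary pixel-center membership.** Each voxel is attributed wholly to one
  class; there is no partial-volume weighting. A voxel straddling the fat
  boundary reports an averaged HU and is classified by that average. This
  matches the per-pixel decision a threshold display makes, and it is the
  reason recovered volumes carry an O(pixel size) discretization error for
  shapes that do not align with the grid.
* **Depth = reconstruction increment, not slice thickness.** With 1.25 mm
  slices reconstructed every 1 mm, consecutive slices overlap by 0.25 mm;
  multiplying per-slice areas by the thickness would double-count that
  overlap (a factor of exactly 1.25 here). The increment is derived from the
  slice positions themselves (median consecutive gap along the dominant
  patient axis), not from header fields. Since acquisition documentation
  often leaves ambiguous which convention a legacy tool used,
  `depth_mode = "thickness"` is exposed to reproduce the other reading; on
  the default geometry the two differ by exactly the factor 1.25.

## Rasterization and its tie-break

A pixel center is inside a polygon iff a ray from it crosses the polygon
boundary an odd number of times (even–odd rule). Centers exactly on an edge
are a measure-zero set but occur constantly in practice (ROIs drawn on
pixel boundaries), so the test point is perturbed deterministically by
(+ε, +ε) with ε = 2⁻²⁰ px. This removes vertex/horizontal-edge special
cases, is identical across platforms, and changes counts only for polygons
passing exactly through centers. Overlapping polygons on a slice are
OR-combined; there are no subtractive ROIs or holes. Polygon parts outside
the image are clipped with a warning. The production implementation is a
scanline (one crossing computation per image row, parity by sorted
crossings); tests pin it voxel-for-voxel against a per-pixel ray-casting
oracle written independently.

## The phantom generator

Real patient series for the motivating application are not redistributable,
so validation rests on synthetic phantoms: box or cylinder inserts of known
HU and closed-form volume (box: product of extents; cylinder: πr²h) inside
a +40 HU soft-tissue background, written as genuine DICOM Part-10 files
with slope 1 / intercept −1024 so stored values reproduce the requested HU
exactly. Defaults emulate a routine clinical geometry: 1.25 mm slice
thickness at a 1 mm reconstruction increment, isotropic in-plane spacing.
Insert membership is evaluated at pixel centers with half-open extents
`[c − e/2, c + e/2)`, so a voxel-aligned box has an exact integer voxel
count and exact-recovery tests are meaningful. Optional Gaussian HU noise
(seeded) is truncated at ±3.5 SD, so moderate noise cannot push the +40 HU
background across the −50 HU boundary; larger SDs deliberately can.

What the phantoms do *not* emulate: anatomy, partial-volume blur at tissue
interfaces, beam hardening, scanner reconstruction kernels, or ROI-drawing
variability. Passing phantom tests therefore demonstrates that the counting
machinery is exact and convergent, not that the adipose HU window is the
right segmentation for any particular anatomy.

## Convergence, and why it is measured placement-averaged

For a fixed smooth shape, pixel-center counting converges to the analytic
volume as the pixel size shrinks. The error of a *single* placement,
however, oscillates with the shape's alignment to the pixel lattice (the
lattice-point-counting effect familiar from the Gauss circle problem):
half-lattice-aligned cylinders can produce identical relative errors at two
consecutive resolutions, and arbitrary centers show non-monotone dips.
`convergence_study()` therefore reports, at each pixel spacing, the mean
absolute relative error over a small seed-fixed set of random sub-voxel
placements of the same cylinder — the standard way to measure grid
convergence free of alignment artifacts. Measured this way the error
decreases strictly across 2, 1, 0.5, 0.25 mm and is below 2% from 0.5 mm
down (the suite asserts both).

## Validation statistics

The agreement and comparison tools mirror a common clinical-validation
workflow:

* `bland_altman()` reports the mean of paired differences (bias) and
  bias ± 1.96·SD (limits of agreement), with the sample (n−1) SD.
* `compare_groups()` gates on per-group Shapiro–Wilk normality at
  α = 0.05: two normal groups get Welch's t, otherwise a two-sided
  Mann–Whitney U; three or more get one-way ANOVA or Kruskal–Wallis. The
  gate's verdicts and the chosen test are recorded in the result — a
  pipeline that silently switches tests is not auditable. (For two groups
  of paired measurements a `paired` flag selects the paired variants, but
  the default is unpaired, matching how such comparisons are often
  reported.) No multiple-testing correction is applied; callers comparing
  many subgroups should add their own.
* `correlate()` is two-tailed Spearman, labelled on the Chan scale
  (|r| = 1 perfect, ≥ 0.8 very strong, ≥ 0.6 moderate, ≥ 0.3 fair, ≥ 0.1
  weak, else negligible). Exact monotone inputs are snapped to ±1 (rank
  arithmetic otherwise leaves 1 − 1e−16, which would mislabel a perfect
  correlation as very strong).

The type-I error of the gated pipeline is itself checked by simulation:
under a three-group null the rejection rate at α = 0.05 over 1000
repetitions must land in (0.03, 0.07). This guards against the gate
distorting the nominal level.

## Numerical choices and degenerate inputs

* HU ranges may have infinite endpoints, so the complement of `[lo, hi]`
  is expressible as two rays; tests assert the exact partition
  `N_sub(range) + N_sub(below) + N_sub(above) = N_ROI`.
* An ROI set with *no* polygons anywhere is an error ("empty region"), but
  an outlined region whose threshold selects nothing legitimately reports
  0 cm³ and 0%; a 0/0 percentage returns 0 with a warning.
* Zero-area (collinear) polygons rasterize to empty masks; polygons with
  fewer than 3 vertices or repeated consecutive vertices are rejected at
  construction.
* Series are sorted by position along the patient axis with the largest
  positional variance (robust to mild obliquity; no gantry-tilt or
  multi-frame support), with InstanceNumber as tie-break; duplicate
  positions are an error, irregular gaps a warning with the median used.

## Problem sizes in the shipped checks

The test-suite and acceptance-script phantoms use 32–52 px grids, 20-slice
stacks, 20 random phantoms and 200 random polygons for oracle equivalence,
100 randomized invariant cases, and 1000 null simulations for the type-I
calibration — sizes chosen so the whole validation runs in well under a
minute while every property is exercised at full strength; all scale up
linearly if heavier verification is wanted.
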