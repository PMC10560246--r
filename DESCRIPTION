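Package: ctsubvol
Title: Hounsfield-Unit Sub-Volume Quantification in CT Series
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Semi-automatic quantification of tissue sub-volumes in computed
    tomography. Reads an axial DICOM CT series and per-slice polygon regions
    of interest, rasterizes the polygons to voxel masks, selects voxels whose
    calibrated attenuation falls in a Hounsfield-unit interval (default the
    adipose range -150 to -50 HU), and converts voxel counts to volumes in
    cubic centimeters. Includes a synthetic CT phantom generator with
    analytically known ground-truth volumes, an independent brute-force
    quantifier for equivalence testing, Bland-Altman method agreement,
    normality-gated group comparisons, Spearman correlation with the Chan
    strength labels, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
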