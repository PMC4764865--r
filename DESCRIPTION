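Package: microCTseg
Title: Semi-Automatic Segmentation and Volumetric Morphometry for
    Micro-CT Slice Stacks
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for extracting soft-tissue structures from 8-bit
    greyscale micro-CT slice stacks, developed around the workflow used
    for stained insect (bumblebee) brain scans: base/top intensity
    thresholding with automatic threshold selection from bimodal
    pixel-intensity histograms, keyframe closed-contour annotation with
    linear contour interpolation across slices, rasterization to binary
    masks, connected-component island removal and Gaussian mask
    smoothing, and voxel-count volumetrics. Includes the validation
    statistics used to qualify such measurements (between-method
    agreement, test-retest repeatability, left-right paired symmetry
    regression, and allometric regression against body size), plus a
    synthetic phantom generator with analytic ground truth so the full
    pipeline can be exercised and calibrated without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
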