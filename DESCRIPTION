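Package: mvsmlm
Title: Multi-Camera Single-Molecule Localization Microscopy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis stack for single-molecule localization microscopy
    (SMLM) acquired on one or more CMOS/sCMOS cameras. Provides per-pixel
    camera calibration and photo-electron conversion, a synthetic frame
    simulator with Poisson shot noise and per-pixel Gaussian read noise,
    analytic Gaussian and measured cubic-spline point-spread-function (PSF)
    models, SNSMIL-style spot detection, maximum-likelihood fitting under
    the sCMOS per-pixel noise model for single-plane and joint multiplane
    (biplane/quadplane) data, inter-camera affine registration, Cramer-Rao
    bound calculators (Mortensen integral and Fisher information), bead
    tracking and precision statistics, drift correction by sub-image
    cross-correlation, spectrally-resolved dye classification by k-means,
    and super-resolution image rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
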