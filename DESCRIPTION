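Package: duoscope
Title: Calibration and Dual-Channel Analysis for Focus-Tunable Miniscope Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calibration and analysis toolkit for dual-color miniature
    fluorescence microscopes with an electrowetting tunable lens. Estimates
    focal-plane depth from 45-degree depth-of-field target sweeps via an
    envelope-modulated first-harmonic model and fits the linear control
    signal to depth relationship; detects grid intersections to quantify
    radial distortion and fits the Petzval field-curvature sphere by linear
    regression; measures lateral and axial chromatic aberration from
    two-channel fluorescent bead volumes; and provides a dual-channel
    calcium-imaging pipeline (de-interleaving, median filtering,
    Fourier-based rigid motion correction, static-channel segmentation,
    ROI trace extraction, and cross-channel neuron matching by footprint
    overlap). A synthetic-data generator with full ground truth makes every
    stage testable without acquired data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
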