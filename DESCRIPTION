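Package: fusmark
Title: Quantifying Biopsy-Marker Perturbation of MR-Guided Focused Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how implanted breast biopsy
    markers perturb MR-guided focused ultrasound (MRgFUS) therapy.
    Reconstructs volumetric acoustic pressure fields from planar hydrophone
    scans by angular-spectrum projection and computes focal-spot metrics
    (peak pressure, half-maximum focus volume, displacement, insertion
    loss); converts complex MR image series to temperature maps via proton
    resonance frequency (PRF) shift thermometry, accumulates CEM43 thermal
    dose and extracts treatment-volume statistics; segments marker
    signal-void artifacts by a noise-referenced threshold rule; and
    estimates ablated volume from serial gross-pathology slices with
    combined standard uncertainty. A physics-grounded synthetic-data
    generator (Rayleigh-integral focused-bowl source with occlusion
    screens, heat-kernel temperature evolution, dipole susceptibility
    artifacts, ellipsoid slice stacks) provides ground truth for every
    stage so the whole chain runs and is verified without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    Rcpp,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    RNifti,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
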