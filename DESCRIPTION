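Package: macroGP
Title: Macrophage Phenotyping by Membrane-Order Imaging, Expression and
    Marker Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested re-analysis pipeline for three-way macrophage
    phenotyping (M0/M1/M2). Implements ratiometric generalized-polarization
    (GP) membrane-order imaging with LUV-based calibration-factor estimation,
    pixel-wise GP maps with HSB rendering, automated ring-shaped membrane
    segmentation, 2^-DeltaDeltaCq relative expression quantification with
    standard-curve primer-efficiency checks, surface-marker MFI profiling,
    a shared two-group statistical engine (pooled/Welch t, F variance test,
    eta-squared effect size, confidence intervals), and marker-based
    phenotype classification (PCA, multinomial logistic regression, GP
    thresholds). A seeded synthetic-data module emulates the study design
    (two-channel membrane images with known GP, calibration vesicles,
    Cq and MFI tables) so every stage is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tiff,
    png,
    yaml,
    nnet,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
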