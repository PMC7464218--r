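Package: cnpquant
Title: Segmentation and Grid-Based Quantification of Retinal Capillary
    Non-Perfusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying retinal capillary non-perfusion (CNP) on
    ultra-wide-field fluorescein angiography. Provides a seeded synthetic
    angiogram generator with known CNP ground truth, deterministic
    preprocessing with stochastic training-time augmentation, a U-net style
    encoder-decoder trained with a generalized Dice objective to produce
    per-pixel CNP probability maps, a fovea-centred concentric-ring grid that
    converts dense masks into a standardized 72-segment perfusion topography,
    and agreement statistics (Cohen's kappa, intraclass correlation, Dice,
    fold-averaged ROC and precision-recall curves) for comparing graders and
    automated segmentations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
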