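Package: camseg
Title: Weakly Supervised Tumor Segmentation on PET/CT via Class Activation Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weakly supervised segmentation of FDG-avid tumor lesions on
    PET/CT image slices from slice-level binary labels. A convolutional
    slice classifier is trained on paired PET (SUV) and CT (HU) channels;
    class activation maps (classic CAM, GradCAM, GradCAM++, ScoreCAM)
    localize the evidence for the tumor class; an adaptive two-threshold
    routine (CAM threshold plus an SUV percentile inside the candidate
    region) turns each map into a binary segmentation. Includes a fully
    supervised 2D U-Net and a global SUV-percentile baseline, grid-search
    tuning of the per-method thresholds, per-subject biomarkers (3D Dice,
    metabolic tumor volume, total lesion glycolysis), cohort statistics
    (median/IQR, two-way agreement intraclass correlation), and a synthetic
    PET/CT phantom generator so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    EBImage,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
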