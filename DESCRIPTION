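Package: nodeval
Title: Localization and Segmentation Evaluation for 3D Lymph-Node Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instance-level evaluation of automated lymph-node segmentation
    against manual ground truth on co-registered 3D CT label masks.
    Extracts node instances by connected-component analysis, measures
    RECIST 1.1 short-axis diameters on the axial plane, matches predictions
    to ground truth by per-node sensitivity, computes detection metrics
    (recall, precision, F1, false positives per scan) and false-positive/
    false-negative-filtered segmentation metrics (global Dice, average
    Hausdorff distance in mm), stratifies results by node size and
    metastatic status, and runs the accompanying nonparametric group
    statistics. A synthetic phantom-cohort generator with a configurable
    degradation model makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
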