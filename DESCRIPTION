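Package: cemarker
Title: Peptide Biomarker Discovery from CE-MS Peptidomic Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for capillary electrophoresis mass
    spectrometry (CE-MS) peptidomics: synthetic cohort simulation with planted
    differential peptides, peak-list quality control, mass and migration-time
    calibration against reference peptides, internal-standard amplitude
    normalization, cross-sample peptide clustering with mass- and
    time-dependent tolerances, rank-based differential marker discovery with
    Benjamini-Hochberg correction, maximal-margin (linear SVM) biomarker panel
    classification with precision-derived diagnostic cut-offs, theoretical
    monoisotopic mass and migration-time validation of peptide
    identifications, and diagnostic performance evaluation with exact binomial
    confidence intervals and ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
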