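Package: rpindex
Title: Genotype-Based Prediction of Radiation Pneumonitis with Stability-Selected Elastic Net
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for building and applying the Radiation
    Pneumonitis Index (RPI), a genotype-based risk score for grade >= 2
    radiation pneumonitis after thoracic radiotherapy. Provides reference-
    relative 0/1/2 SNP dosage encoding, per-site quality control (mean
    GenCall score, missingness, minor allele frequency, exact Hardy-Weinberg
    test, multi-allelic exclusion), clinical-factor screening (exact Fisher
    and Mann-Whitney U tests), penalized logistic regression by elastic-net
    coordinate descent with per-feature penalty factors and 10-fold
    cross-validated lambda selection, bootstrap stability selection with a
    majority-inclusion rule, RPI scoring with threshold classification, and
    a synthetic cohort generator that emulates the genotype/phenotype
    structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    withr
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
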