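Package: chmnat
Title: Natural History and Genotype-Phenotype Analysis of Choroideremia Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-sectional natural-history analysis of
    choroideremia (CHM) cohorts: conversion of Snellen and semiquantitative
    visual acuities to logMAR, better-eye selection, decade-stratified
    summaries, detection of the critical age separating the stable and
    progressive phases of visual decline by iterative decade pooling with
    Kruskal-Wallis and Dunn tests, biphasic linear regression of acuity and
    visual-field width on age, Kaplan-Meier analysis of symptom onset by
    mutation class, intereye rank correlation, HGVS-style CHM variant
    classification and mutation-spectrum comparison, two-state unfolding
    propensities from protein stability free-energy changes, and a
    time-to-detectable-change calculator for trial design. A synthetic
    cohort generator reproduces the statistical structure of published
    CHM cohort data so every stage is testable without patient-level data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
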