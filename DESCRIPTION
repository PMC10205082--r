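Package: synergait
Title: Tibiofemoral Kinematics and Muscle Synergy Analysis for Knee Implant Stability Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for comparing stable and self-reported
    unstable total knee arthroplasty (TKA) knees from implant-pose derived
    kinematics and surface electromyography (EMG). Computes tibiofemoral
    joint angles in the Grood-Suntay joint coordinate system and condylar
    anterior-posterior translations from per-frame rigid-body poses,
    normalizes gait cycles, extracts muscle synergies by non-negative matrix
    factorization with multiplicative updates, functionally classifies them
    by k-means clustering, and summarizes activation timing with full width
    at half maximum and circular centre of activity statistics. Group
    comparisons use pooled two-sample t-tests with Bonferroni correction,
    chi-squared tests, one-way ANOVA, and permutation-based one-dimensional
    statistical parametric mapping over kinematic time series. A synthetic
    cohort generator with known ground truth makes every stage testable
    without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    patchwork,
    withr
Config/testthat/edition: 3
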