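Package: gaitrel
Title: Test-Retest Reliability of IMU-Derived Gait Stability, Symmetry and
    Smoothness Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for wearable inertial-sensor (IMU) gait assessment in
    neurological populations: reads raw tri-axial acceleration and angular
    velocity trials, performs gravity alignment, gyroscope bias removal and
    zero-phase Butterworth filtering, segments strides from the shank angular
    velocity, and computes per-trial stability (normalized RMS), symmetry
    (improved harmonic ratio) and smoothness (log dimensionless jerk) indices.
    A reliability layer turns paired test/retest index tables into
    ICC(3,1)/ICC(A,1) estimates with confidence intervals, standard error of
    measurement and minimal detectable change, with paired-difference tests
    and subgroup comparisons. A synthetic gait-cohort generator with analytic
    ground truth supports validation of every stage without access to patient
    recordings.
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
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
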