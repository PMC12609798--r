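Package: repforce
Title: Force-Time Feature Extraction and Perceived-Exertion Estimation for
    Isokinetic Resistance Exercise
Version: 0.1.0
Authors@R:
    person("repforce", "developers", email = "repforce@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating end-of-set ratings of perceived exertion
    (RPE, OMNI-RES 0-10) from load-cell force-time curves recorded during
    repeated isokinetic bench-press sets. Includes a seeded synthetic cohort
    generator emulating fatigue progression across sets, zero-phase
    Butterworth preprocessing and repetition segmentation, per-repetition
    biomechanical feature extraction (peak force, RMS, work, time to peak,
    rate of force development, distribution moments) with inter-set relative
    and composite features, correlation-based feature screening, random
    forest / gradient boosting / ridge regressors with median-based ordinal
    cut-point discretization, and subject-grouped cross-validated evaluation
    with tolerance accuracies and Bland-Altman agreement analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
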