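Package: mmtstrength
Title: Predicting Maximum Isometric Strength Moments from Theoretical
    Grade 3 Gravitational Moments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies manual muscle testing (MMT) for hip and knee
    flexion/extension by linking the theoretical Grade 3 strength moment
    (the gravitational moment on the limb segment, computed from body mass,
    segment lengths and anthropometric segment parameters) to the maximum
    isometric strength moment measured with a handheld dynamometer.
    Provides the closed-form biomechanical moment model, per-age-group
    regression and ANCOVA analysis (parallelism, common slope, adjusted
    pairwise comparisons), a clinical predictor built on published
    age-group regression coefficients, and a seeded synthetic-cohort
    generator calibrated to the published group statistics so that the
    whole pipeline is testable without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    emmeans,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
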