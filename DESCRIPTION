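Package: kcindex
Title: Automated General Movement Assessment from Four-Limb Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a composite movement score (the KC index) for infant
    general movement assessment from four-limb tri-axial accelerometer
    recordings. The pipeline synchronizes per-device clocks, removes the
    gravitational component with a zero-phase high-pass filter, extracts
    per-limb kurtosis of the first principal component of acceleration and
    inter-limb jerk cross-correlation, combines them with cohort range
    normalization, and selects a classification cutoff by ROC analysis with
    Youden's index and bootstrap confidence intervals. A synthetic
    movement-burst simulator generates labelled cohorts so every stage can
    be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    e1071,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
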