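Package: toeforce
Title: Analysis of Great Toe Extension Strength Force-Time Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing isometric great toe extension strength (GTES)
    force-time curves recorded by portable toe dynamometers. Reads two-column
    device trial files (time, force) sampled at 50 Hz, applies the end-of-trial
    last-value imputation rule, and extracts the five curve parameters used to
    characterise toe strength: peak force, rise time to 80% of peak, average
    force after the 80% crossing, percentage of samples at or above that
    average, and the rate of force development. Provides group statistics
    (descriptives, Welch t-tests, type-II two-way ANOVA, Pearson correlations
    with normality flags), raw-curve classification by age group or sex with
    k-nearest neighbours, support vector machines and random forests under
    split and k-fold evaluation, and a calibrated synthetic cohort generator
    with ground-truth manifests for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    class,
    e1071,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
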