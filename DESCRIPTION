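Package: insolegait
Title: Dynamic Plantar Pressure Analysis for Knee Osteoarthritis Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for analysing dynamic plantar pressure
    recorded by an eight-region wearable insole sampled at 20 Hz. Provides a
    synthetic gait simulator with configurable group effects, stance-phase
    segmentation with a bimodality validity screen and midgait trimming,
    extraction of a frozen 210-feature catalogue (regional peak pressures,
    pressure gradients, impulses, centre-of-pressure statistics, whole-foot
    curve parameters and left-right symmetry indices), normality-routed
    univariate filtering with a forward wrapper search, and five classifier
    backends with seeded tuning and confusion-matrix evaluation for
    separating radiological knee osteoarthritis from non-radiological cases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    class,
    e1071,
    randomForest,
    rpart,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
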