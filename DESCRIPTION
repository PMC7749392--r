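Package: glutenscore
Title: Functional Quality Prediction for Vital Wheat Gluten
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to predict the baking quality of vital wheat gluten from
    rapid small-scale physicochemical tests. Extracts features from gluten
    aggregation (torque-time) curves, including an asymmetric Chesler-Cram
    peak-function fit, and from microscale dough extension (force-distance)
    curves; integrates gel-permeation HPLC chromatograms into gliadin and
    glutenin fractions; classifies samples into quality classes by
    hierarchical clustering of microbaking specific volumes; screens
    features by Spearman rank correlation; and predicts quality with a
    quantile-binned, correlation-weighted scoring system. A synthetic-data
    generator produces sample panels with the cross-modal correlation
    structure the analysis assumes, so the whole pipeline is testable
    without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
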