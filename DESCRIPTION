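Package: ehrscreen
Title: Screening Longitudinal EHR Laboratory Data for Pre-Event Biomarker Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for screening routinely collected blood and
    urine laboratory measurements in electronic health records (EHR) for signals
    that precede a clinical event such as ischemic stroke. Provides matched
    case-control cohort construction with exclusion policies, sex- and
    age-adjusted z-score normalisation of analyte values, association-rule
    mining of extreme-value itemsets with an FP-Growth miner and a
    control-resampling null, lowess-based trajectory trend-onset detection,
    per-analyte logistic and Cox proportional-hazards association analyses with
    Kaplan-Meier proportionality checks, and a benchmark of five tabular input
    representations (including informative-missingness binary statements) under
    logistic regression, k-nearest-neighbour and random-forest classifiers.
    Includes a fully seeded synthetic-EHR generator that plants known trends,
    effects and hazards so that every stage can be validated by recovery of
    simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    randomForest,
    class,
    pROC
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    nortest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
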