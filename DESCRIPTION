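Package: pniflow
Title: Psychoneuroimmune Longitudinal Cohort Simulation and Hybrid
    Temporal Prediction for Athlete Nutrition Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying nutrition-psychology-immunity dynamics in
    longitudinal athlete cohorts. Generates reproducible synthetic bi-weekly
    panels with planted psychoneuroimmune structure (dietary-pattern groups,
    psychological-to-immune temporal lags, a serial diet-psychology-cortisol-
    immunity mediation chain, and resilience-subgroup response dynamics);
    implements a cleaning and feature-engineering pipeline with chained-
    equation imputation and leakage-safe forward-chaining temporal splits; a
    hybrid recurrent/gradient-boosting predictor with attention-weighted
    fusion; sampling-based Shapley attribution; and the accompanying
    inference machinery: lag cross-correlation scans, canonical correlation,
    serial mediation with bootstrap confidence intervals, ARIMA order
    selection, mixed-effects subgroup models, and response-trajectory
    characterisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite,
    yaml,
    xgboost,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
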