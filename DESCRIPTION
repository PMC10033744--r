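Package: epiasthma
Title: Asthma Phenotyping, Dietary Glycemic-Index Scoring, and
    Exposure-Outcome Association Analysis for ISAAC-Style Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-sectional asthma epidemiology built around
    ISAAC-style questionnaire data: classification of subjects into the
    asthma taxonomy (ever, atopic, current, current-atopic, and the
    wheeze-, cough-, and exercise-induced variants, with skin-prick-test
    atopy at the 3 mm wheal threshold), the Quality of Diet based on
    Glycemic Index Score (QDGIS) computed from a 16-item food-frequency
    block, contingency-table odds ratios with Wald confidence intervals,
    and multivariable logistic regression fitted by iteratively
    reweighted least squares for adjusted odds ratios. A synthetic-cohort
    generator reproduces the statistical structure of a large
    cross-sectional survey (categorical marginals, a logistic outcome
    model, symptom and skin-prick-test submodels, and
    missing-completely-at-random gaps) so that every stage of the
    pipeline can be exercised and validated without access to
    individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
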