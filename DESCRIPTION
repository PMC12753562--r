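Package: tmcohort
Title: Time-Matched New-User Cohort Studies from Longitudinal Claims Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A reusable, tested pipeline for retrospective time-matched
    new-user cohort studies built from longitudinal claims tables:
    synthetic claims generation with known confounding structure and a
    known true exposure hazard ratio, cohort construction with time-matched
    control selection (addressing immortal time bias), baseline covariate
    extraction from code dictionaries, fully conditional specification
    multiple imputation of missing BMI and smoking data, standardized
    mortality ratio weighting (SMRW) from propensity scores with covariate
    balance diagnostics, drug exposure episode construction with gap/grace
    periods, claims-based outcome ascertainment (diagnosis plus treatment
    co-occurrence), and weighted Cox proportional-hazards and Kaplan-Meier
    estimation pooled across imputations by Rubin's rules, under both
    intention-to-treat and per-protocol follow-up.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    survival,
    MASS,
    glmnet,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
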