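Package: mcds
Title: Modified Chronic Disease Score from Outpatient Drug Prescriptions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Modified Chronic Disease Score (M-CDS), a
    drug-based comorbidity index that predicts one-year mortality from
    outpatient pharmacy-claims data alone. Maps two years of dispensed
    prescriptions (ATC-coded) to binary chronic-condition flags via a
    threshold-based rule table, scores patients with published integer
    weights, and stratifies them into six risk classes. Also re-derives
    weights on any cohort with an L1-penalised Cox model (10-fold
    cross-validation, one-standard-error rule, post-selection refit), finds
    risk-class boundaries with an ordinal CHAID classification tree, and
    validates discrimination with ROC/AUC (DeLong confidence intervals and
    paired tests), Kaplan-Meier curves and the log-rank test. A synthetic
    pharmacy-claims simulator with calibrated baseline mortality makes the
    whole pipeline testable without access to administrative data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    glmnet,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
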