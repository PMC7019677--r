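Package: salivadx
Title: Salivary mRNA Biomarker Evaluation for Oral Cancer Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnostic-biomarker analysis pipeline for salivary mRNA panels
    in oral squamous cell carcinoma (OSCC) screening: relative qPCR
    quantification on the 2^-ddCt scale, per-gene group summaries with a
    control mean-minus-SD "low level" cancer-call rule, empirical ROC/AUC
    evaluation with stratified bootstrap confidence intervals and Youden
    operating points, a greedy AUC-ordered logistic risk-score algorithm for
    multi-marker panel combination, and age-stratified re-analysis. Includes
    a seeded synthetic-cohort generator calibrated to published two-group
    summary statistics so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    glmnet,
    withr,
    optparse
Config/testthat/edition: 3
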