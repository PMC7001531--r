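Package: strokemet
Title: Recovery-Stratified Targeted Amino Acid Metabolomics for Stroke
    Rehabilitation Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for relating targeted serum amino-acid profiles to
    functional recovery after ischemic stroke. Scores rehabilitation
    outcome by Montebello Rehabilitation Factor Score (MRFS) efficiency,
    stratifies extreme good/poor recoverers, normalizes targeted peak-area
    matrices (per-sample median scaling, half-minimum imputation, unit
    variance scaling), fits two-class partial least-squares discriminant
    analysis (PLS-DA) with R2Y/Q2Y quality metrics, permutation validation
    and VIP-based biomarker selection, and ranks every biomarker-panel
    subset by repeated stratified 10-fold cross-validated AUC. Includes a
    synthetic cohort generator with known ground truth so the full
    workflow is testable without patient data.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    mixOmics,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
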