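Package: poafr
Title: Detection and Validation of Postoperative Atrial Fibrillation from
    Hospital Discharge Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based detection of new-onset postoperative atrial
    fibrillation (POAF) after cardiac surgery from hospital administrative
    data (ICD-10-CA discharge diagnoses and CCI procedure codes with a
    multi-year look-back), together with the diagnostic-accuracy machinery
    needed to validate such case-detection algorithms against a chart-review
    reference standard: exact binomial confidence intervals, McNemar and
    generalized-score predictive-value comparisons, site-stratified
    analysis, inversion of rounded published accuracy tables into integer
    confusion matrices, and a synthetic discharge-abstract generator with
    closed-form expected accuracies so the whole pipeline is testable
    without access to real hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
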