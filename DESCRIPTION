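Package: pharmscreen
Title: Synthetic Cell-Line Viability Screens, Dose-Response Metrics, and
    Elastic-Net Biomarker Stability Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for simulating and analysing large-panel cell-line
    viability screens. Generates synthetic screens with planted genomic
    ground truth (multi-tissue cohorts, expression/copy-number/mutation
    tables, 384-well plate data with control and blank wells); applies
    plate-level quality control (control-well coefficient of variation,
    signal-over-noise, response directionality); fits bounded
    four-parameter logistic dose-response curves to derive IC50, AUC and
    Emax; assembles multi-omic design matrices; runs repeated
    leave-10-percent-out elastic-net stability selection to score
    sensitivity and resistance biomarkers; and tests biomarker lists for
    interaction-network connectivity (permutation null) and
    annotation-term enrichment (hypergeometric with Benjamini-Hochberg
    adjustment).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
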