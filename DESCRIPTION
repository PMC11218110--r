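Package: pdblood
Title: Blood-Based Biomarker Discovery for Neoadjuvant PD-1 Blockade Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovering blood-based biomarkers of
    response to neoadjuvant PD-1 blockade in non-small-cell lung cancer.
    Implements marker-gene immune-cell deconvolution with correlation-filtered
    marker panels and log2 abundance scores, differential-expression testing
    with fold-change and FDR thresholds plus Common/Unique set algebra across
    contrasts, hierarchical-clustering stratification of pre-treatment
    samples, PASS-variant filtering with driver/pathogenicity gene ranking and
    mutation-panel patient stratification, tumor mutational burden comparison,
    and first-principles Kaplan-Meier, log-rank and Cox proportional-hazards
    survival analysis. A synthetic-data module generates cell-type signatures,
    pseudo-bulk mixtures, cohort expression with planted effects, variant
    tables and survival times with known ground truth so every stage is
    testable end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    survival,
    mclust
Config/testthat/edition: 3
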