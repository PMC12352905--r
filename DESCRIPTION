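Package: hnfscore
Title: Gene-Signature Scoring and Outcome Association for
    GI-Transcriptome-Positive Prostate Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes summed z-score gene-signature scores (an 11-gene
    HNF1A/HNF4G gastrointestinal-lineage panel and a combined androgen-receptor
    panel) from bulk and single-cell expression matrices, stratifies samples at
    fixed score thresholds, and associates strata with treatment response
    (Fisher's exact test), time on treatment and overall survival
    (Kaplan-Meier / log-rank), immunohistochemistry H-scores, and xenograft
    growth-response metrics. Includes synthetic-data generators emulating the
    cohort, single-cell, tissue-microarray and tumor-growth designs the
    analyses assume, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Matrix,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
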