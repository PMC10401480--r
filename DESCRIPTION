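Package: surfnom
Title: Nomination of Cell-Surface Therapeutic Targets from RNA-seq Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-step filtering pipeline that nominates cell-surface
    therapeutic target candidates specifically overexpressed in
    neuroendocrine prostate cancer (NEPC) relative to benign prostate,
    localized adenocarcinoma, castration-resistant prostate cancer (CRPC)
    and a panel of normal tissues, at gene and transcript-isoform level.
    Includes TPM/FPKM quantification from raw counts, a self-contained
    negative-binomial Wald differential-expression engine with
    median-of-ratios normalization and Benjamini-Hochberg adjustment,
    surface-protein catalog construction from gene lists and GO
    associations, a tissue-breadth specificity filter over median
    expression, and a fully seeded synthetic-cohort generator with a
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
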