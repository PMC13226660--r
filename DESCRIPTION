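Package: anchorscreen
Title: Anchor-Gene Co-Expression Screening and Genotype-Dependent
    Response Classification for Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable implementation of an anchor-gene candidate discovery
    pipeline for bulk and single-cell transcriptomics: Pearson-correlation
    screening against anchor genes across two tissues with four-set
    intersection, min-max scaled tissue-distribution correlation and
    hierarchical module extraction, recovery-curve AUC gene-set scoring of
    single-cell clusters with small-cluster exclusion, and a fasting/refeeding
    response classifier (blunted vs enhanced in a knockout genotype) with
    hypergeometric over-representation testing under Benjamini-Hochberg
    correction. Includes a seed-deterministic synthetic-data generator with
    planted ground truth so every stage is testable end-to-end without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
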