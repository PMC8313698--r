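Package: loycite
Title: Mosaic Loss of Chromosome Y Detection and Differential Abundance in
    CITE-seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infrastructure for studying mosaic loss of chromosome Y (LOY) in
    single leukocytes profiled with CITE-seq. Reads 10x-dialect RNA and
    antibody-derived-tag (ADT) count matrices, applies per-cell quality
    control, normalizes RNA (log, fixed scale factor) and ADT (centered
    log-ratio), classifies cells as LOY by absence of transcripts from the
    male-specific region of chromosome Y, assigns leukocyte types from
    surface-marker evidence, and tests for LOY-associated shifts in CD99
    mRNA and protein abundance with confounder-adjusted hurdle and logistic
    regression models and Benjamini-Hochberg correction. Includes a seeded
    negative-binomial CITE-seq simulator with ground-truth labels so the
    whole chain is testable without access to raw sequencing data.
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
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
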