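Package: sexdimorph
Title: Sex-Differential Expression Analysis of Cortical Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting sexually dimorphic gene
    expression in repeated-measures brain expression cohorts. Provides
    expression filtering, correlation-based outlier removal, quantile
    normalization and sex-balanced sample matching; per-gene sex-contrast
    estimation by generalized least squares with a consensus intra-subject
    correlation and empirical-Bayes moderated t-statistics; dual gene-set
    over-representation analysis (thresholded two-sided Fisher tests and
    threshold-free directional binomial shift tests against curated
    backgrounds); cross-dataset fold-difference concordance; and a
    synthetic-cohort generator with ground-truth tables so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    jsonlite
Config/testthat/edition: 3
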