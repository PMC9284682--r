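Package: plowbatch
Title: Quality-Aware Batch Effect Detection and Correction for RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects batch effects in bulk and single-cell RNA-seq datasets
    from per-sample low-quality probabilities (P_low) using a tie-corrected
    Kruskal-Wallis rank test, quantifies how strongly quality aligns with the
    biological design (design bias, a rescaled Pearson gamma), corrects
    expression data by confounder-adjusted principal component analysis with
    P_low and/or known batch labels as confounders, removes quality outliers
    by a largest-gap rule, and scores corrections with cluster validation
    indices (Dunn index, Pearson gamma, within/between distance ratio).
    Includes a negative-binomial count simulator with quality-coupled batch
    artifacts so the whole workflow is testable without external data, plus
    size-factor normalization and a rank-based differential expression stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
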