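Package: cernascreen
Title: Competing Endogenous RNA Network Screening from Stage-Structured
    RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring lncRNA-miRNA-mRNA competing endogenous RNA
    (ceRNA) networks from bulk RNA-seq count matrices collected across
    developmental stages. Covers novel-lncRNA retention filtering and
    positional classification against a coding annotation, FPKM and
    median-of-ratios normalization, sample-level QC (PCA, sample
    correlation), a negative-binomial exact differential-expression test
    with fixed dispersion, hypergeometric over-representation analysis, the
    three-step ceRNA screen (Spearman anti-correlation of miRNA-target
    edges, Pearson co-expression of candidate pairs, hypergeometric
    shared-miRNA test), network assembly with connectivity ranking and
    Sankey paths, and statistics for qPCR (2^-ddCt) and dual-luciferase
    validation. A synthetic-data generator plants known ceRNA triplets so
    the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    igraph,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    rtracklayer,
    withr
Config/testthat/edition: 3
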