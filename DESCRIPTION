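Package: scgwas
Title: Integrating GWAS Summary Statistics with Single-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A pipeline for linking genome-wide association study (GWAS)
    summary statistics to cell types and cell subsets measured by
    single-cell RNA sequencing. It scores gene- and pathway-level genetic
    association from SNP summary statistics and block-wise linkage
    disequilibrium, runs summary-based transcriptome-wide association
    tests in single and multiple tissues from sparse eQTL weight models,
    estimates polygenic cell-type enrichment with a method-of-moments
    regression and block-bootstrap inference, measures overlap between
    gene sets by Monte-Carlo permutation, computes binned-control cell
    activity scores, differential expression and co-expression summaries,
    and infers simplified ligand-receptor communication with
    non-negative-matrix-factorization communication patterns. A synthetic
    data module generates every input with planted ground truth so the
    whole pipeline is exercisable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
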