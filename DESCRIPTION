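Package: multimorbid
Title: Multimorbidity Atlas from Spatial eQTL-eGene Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a multimorbidity atlas of traits from pleiotropy of
    spatially regulated genes. Starting from GWAS-style SNP-trait
    associations, Hi-C restriction-fragment interaction records and an eQTL
    association table, the pipeline performs an in-silico restriction digest,
    assigns SNPs and collapsed gene models to restriction fragments, derives
    spatial SNP-gene pairs with fragment- and supporting-interaction counts,
    calls spatial eQTL-eGene pairs under Benjamini-Hochberg FDR control with
    cis/trans classification, builds asymmetric phenotype gene-sharing
    matrices with a permutation null, biclusters phenotypes by convex
    biclustering along a regularisation path with hold-out validation, and
    scores per-cluster gene commonality. A synthetic-data generator with
    planted ground truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
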