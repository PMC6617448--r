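Package: methylhub
Title: Integrated Promoter Methylation and Expression Analysis with
    Network Hub Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates paired tumour/normal DNA-methylation (450K-style
    beta values) and RNA-Seq expression matrices to call differentially
    expressed genes and differentially methylated promoter positions,
    classify epigenetically induced (promoter-hypomethylated,
    overexpressed) and epigenetically suppressed (promoter-hypermethylated,
    underexpressed) genes with a negative methylation-expression
    correlation filter, and prioritise hub genes by a per-node
    protein-protein-interaction neighbourhood Fisher enrichment statistic.
    Includes gene-set over-representation with term-crosstalk Jaccard
    edges, Kaplan-Meier and log-rank survival comparison of expression
    groups, and a synthetic-data generator that plants known effects so
    the whole pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
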