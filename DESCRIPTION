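Package: txscale
Title: Scaling and Between-Sample Normalization of Digital Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Between-sample normalization of gene expression matrices from
    digital transcript counting (bulk and single-cell RNA-seq). Implements
    fifteen scaling methods -- total-count (CPM) scaling, percentile scaling
    (upper quartile / upper decile), housekeeping-gene and geNorm-style
    guide-gene scaling, trimmed mean of M-values (TMM), quantile
    normalization, random-gene and mock controls, total-ubiquitous scaling,
    Network Centrality Scaling (PageRank on a gene coexpression-consistency
    network), and an Evolution Strategy that directly maximizes the number
    of uniformly expressed genes -- together with two data-driven evaluation
    metrics: the count of "uniform" genes (coefficient of variation below a
    cutoff) and the decorrelation of sample rankings across gene pairs. A
    synthetic-data generator with known ground-truth scaling factors
    supports end-to-end validation.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
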