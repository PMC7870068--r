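Package: blockcca
Title: Model Discovery for Multi-Block Sparse Canonical Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates two or more sample-by-feature omic blocks (e.g. a host
    transcriptome and a microbiome profile) together with clinical covariates by
    regularized and sparse generalized canonical correlation analysis (RGCCA /
    SGCCA). Rather than fixing the block-interaction design a priori, the package
    enumerates candidate symmetric weight matrices over coarse and fine grids,
    keeps only designs forming a single connected network, ranks them by the
    inner average variance explained (AVE) of their latent components, and
    assesses the stability of competing models by bootstrap resampling of
    samples. Includes Schaefer-Strimmer shrinkage estimation of the per-block
    regularization parameter, block standardization and dummy encoding of
    categorical covariates, AUC evaluation of components as classifiers, a
    synthetic multi-block data generator with planted latent structure for
    validation, and a config-driven pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    yaml,
    jsonlite,
    igraph
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
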