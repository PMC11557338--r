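Package: pairpool
Title: Label-Free Sample Multiplexing Designs and Genotype-Based
    Demultiplexing for Pooled Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and decode label-free pooled single-cell RNA-seq
    experiments for paired tissue samples (for example matched skin and
    PBMC from the same donors). Generates dual and triplet pooling
    layouts whose donor identities are provably decodable from
    genotype-sharing across reactions and, for triplet pools, donor sex
    inferred from Y-chromosome gene expression; verifies identifiability
    by exhaustive enumeration; simulates pooled genotype and expression
    data with ground truth; clusters cells by genotype with a
    binomial-mixture EM and flags cross-genotype doublets; matches shared
    genotypes across reactions; and resolves every cluster to a specific
    sample identity by constraint satisfaction. Includes the standard
    single-cell quality-control filters and normalization used around the
    demultiplexing step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
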