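Package: micronet
Title: Compositional Co-Occurrence Networks and Diversity Analysis for Amplicon Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for two-group 16S rRNA amplicon surveys:
    relative-abundance profiling with low-abundance filtering and rank
    aggregation, alpha diversity (richness, Chao1, Shannon, Faith PD, Good's
    coverage) with rarefaction and exact nonparametric group tests, beta
    diversity (Bray-Curtis, PCoA, NMDS, UPGMA, ANOSIM), empirical-Bayes
    moderated t-tests for differential abundance, and a compositional
    co-occurrence network pipeline: centered log-ratio transform, Pearson
    correlation, random-matrix-theory threshold selection, signed-weight
    networks, fast-greedy modularity clusters, edge-sign architecture,
    positive-to-negative ratio shifts, and eigenvector-centrality keystone
    taxa. Includes a seeded logistic-normal-multinomial community simulator
    emulating a two-condition soil survey design for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    picante,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
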