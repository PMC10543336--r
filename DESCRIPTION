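Package: seedcoex
Title: Stage Discovery, Co-Expression Modules, and Trait Integration for
    Seed Development Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for time-course seed transcriptomes:
    replicate quality control and developmental stage discovery by
    hierarchical clustering on Pearson correlation distance, tau
    tissue-specificity screening against a multi-tissue expression atlas,
    weighted gene co-expression module detection (signed soft-threshold
    adjacency, topological overlap, dendrogram cutting with eigengene
    merging), guide-gene network expansion with hub calling, functional
    category over-representation with Benjamini-Hochberg control, and
    integration of co-expression results with trait associations and
    haplotype groups across an accession panel. Includes seeded synthetic
    data generators with planted ground truth for benchmarking every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
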