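Package: catoolkit
Title: Evolution of Calcium-Signaling Domain Architecture Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomic analysis of the calcium-signaling toolkit
    across genomes. Classifies protein domain architectures (ordered SCOP
    superfamily strings) by calcium-binding content against a curated
    registry of calcium-binding superfamilies, computes per-genome
    repertoire diversity and redundancy statistics, labels architectures
    with functional components of the toolkit (influx, efflux, decoding,
    relay), derives the conserved core toolkit, and reconstructs ancestral
    architecture repertoires on a rooted species tree under Dollo parsimony
    with per-branch gain and loss events. Includes a synthetic-data
    generator that evolves architecture repertoires along a tree with known
    ground truth, so every pipeline stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
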