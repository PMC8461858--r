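Package: semidriver
Title: Cancer Driver-Gene Prioritization by Mutation Effects and
    Semi-Local Network Centrality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate cancer driver genes by combining per-gene
    somatic mutation scores, a gravity-style mutation-impact function between
    gene pairs, and a semi-local (two-hop) centrality computed on a
    protein-protein interaction subgraph restricted to mutated genes and
    differentially expressed genes.  Includes readers for binary gene-by-patient
    mutation matrices and minimal MAF tables, paired tumor/normal expression,
    edge-list PPI networks and benchmark gene lists; a fold-change DEG caller;
    precision/recall/F1 benchmarking against driver-gene catalogs; rare-driver
    flagging; and a seeded synthetic-cohort generator so the whole pipeline is
    testable without external downloads.
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
    tidyr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
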