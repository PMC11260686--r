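Package: diwann
Title: Driver-Gene Mutation Networks from Somatic Mutation Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Network analysis of recurrently mutated cancer driver genes
    from MAF-style somatic mutation tables. Implements the two-step data
    reduction (variant-class exclusion, census-gene recurrence filtering
    and non-census top-frequency filtering), construction of a transformed
    reference sequence restricted to recurrently mutated loci, per-sample
    mutated sequences, and the Directed Weighted All Nearest Neighbors
    (DiWANN) sequence-similarity network built with banded edit-distance
    pruning. Also provides threshold similarity networks, structural
    summaries, Louvain community detection with Fisher-exact annotation
    enrichment, tissue-gene and sample-gene bipartite networks with
    weighted one-mode projections, and a synthetic cohort generator so the
    whole pipeline is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
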