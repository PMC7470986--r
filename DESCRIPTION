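Package: rrescan
Title: Profile-HMM Detection of RiPP Recognition Elements in Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects RiPP recognition element (RRE) domains in protein
    sequences with class-specific profile hidden Markov models (precision
    scanning with tolerant/moderate/stringent bit-score tiers) and with a
    two-stage exploratory pipeline (profile-HMM prefilter, iterative profile
    enrichment, and profile-profile confirmation with a calibrated
    probability). Includes model building from multiple sequence alignments
    with position-based sequence weights and pseudocounts, Gumbel E-value
    calibration, sequence similarity networks with representative-node
    conflation, greedy identity clustering, helix-turn-helix regulator
    filtering, in-silico domain excision, genomic co-occurrence rules for
    biosynthetic gene clusters, and deterministic synthetic-fixture
    generators for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
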