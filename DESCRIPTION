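Package: taxbench
Title: Ground-Truth Benchmarking of Metagenomic Read Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates microbial communities with known per-read taxonomy,
    classifies the reads with a built-in exact k-mer lowest-common-ancestor
    classifier (or ingests Kraken-format output), and scores the result per
    taxonomic rank using a five-way read status scheme (correct, incorrect,
    unclassified at this level, unclassified at any level, truth unknown),
    per-rank classification rates, taxon-level false-positive and
    false-negative counts, and truth-versus-classified abundance concordance
    on log10 percentages. Handles reference genomes with incomplete
    taxonomic lineages (missing family or genus labels, informal species
    names), the central confound when benchmarking against
    metagenome-assembled genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
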