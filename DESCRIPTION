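Package: barcodeforge
Title: Fast Generation of Large-Scale DNA Barcode Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates large libraries of DNA barcodes for multiplexed
    sequencing and high-throughput screens. Each barcode is assembled from a
    batch code, a fixed 2-bp linker, and a target code, so an N-barcode
    library is the cross product of small batch- and target-code sets and
    pairwise Hamming-distance screening scales far below N^2. Candidate
    sequences come from an order-m Markov chain whose repeat probability
    delta^h suppresses homopolymers, with delta tuned by grid search.
    Libraries satisfy a minimum pairwise Hamming distance, a maximum
    homopolymer length, GC-content bounds, and a blacklist of proscribed
    subsequences. Includes a naive single-piece baseline, a benchmark
    harness, an exhaustive/structured library validator, streaming library
    expansion, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
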