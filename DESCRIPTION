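Package: embrep
Title: Embedding-Based Detection of Internal Repeats in Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Detects internal (tandem) repeats in proteins from per-residue
    embedding matrices. A local self-alignment of the embedding, scored by
    cosine similarity, yields suboptimal alignment traces that are enriched
    by one round of transitive composition and accumulated into a dot-plot
    style score matrix.  Off-diagonal score sums estimate candidate repeat
    unit lengths, a position-weighted sliding window localises a
    representative repeat, and a profile-like weighted embedding of that
    window is used to iteratively extract repeat instances, with masking
    between rounds to resolve multiple repeat regions.  The package also
    provides a light-attention binary classifier over residue embeddings
    usable as a fast repeat/non-repeat pre-filter, a synthetic
    planted-repeat embedding generator for controlled benchmarking, a
    protein- and repeat-level evaluation harness, and command-line style
    drivers for detection, simulation, classification and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
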