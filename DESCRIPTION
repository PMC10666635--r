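Package: overlapscan
Title: Intergenic Distances, Overlap Phases and Translational Coupling in
    Prokaryotic Gene Pairs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-scale analysis of unidirectional (serially encoded) gene
    pairs in archaea and bacteria. Extracts adjacent gene pairs from genome
    annotations, classifies their orientation, computes intergenic distances
    (negative for overlapping genes) and overlap phases, enumerates the
    boundary motifs compatible with start/stop codon constraints at short
    overlaps, summarizes distance distributions, decomposes distances across
    taxa into additive COG-pair and phylum effects by least squares, and
    quantifies the enrichment of heteromeric-complex subunits among closely
    spaced gene pairs with a chi-squared test and a double-resampling
    bootstrap. A synthetic-annotation generator provides test data with the
    statistical structure the analysis assumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    rlang,
    stats,
    utils,
    Matrix,
    igraph,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
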