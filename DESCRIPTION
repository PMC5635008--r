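Package: satellitome
Title: Satellitome Mining and B-Chromosome Satellite DNA Analysis from Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Discovery, cataloguing and comparison of satellite DNA families
    (the satellitome) from short-read libraries. Implements iterative mining of
    tandem-repeat monomers by k-mer read clustering and periodicity detection,
    grouping of monomers into variants, families and superfamilies by rotational
    sequence identity, per-family abundance and Kimura two-parameter divergence
    profiling, comparison of B-chromosome-carrying (1B) versus B-lacking (0B)
    genomes via log2 abundance ratios and tandem-structure scans, and the
    statistics used for cytogenetic (FISH) satellite location tables, including
    a B-chromosome symmetry index. A paired synthetic-genome and read simulator
    with planted satellite arrays provides ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    igraph,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
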