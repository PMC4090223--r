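Package: mirdiverge
Title: Comparative Small RNA-Seq Profiling Between Two Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-testable pipeline for comparative
    small RNA sequencing between two pooled libraries: adapter trimming and tag
    collapsing, genome mapping with an annotation cascade, conserved miRNA
    quantification, novel miRNA hairpin discovery under minimum-free-energy and
    MFEI criteria, exact-test differential expression with log2 fold-change
    categories, and rule-based miRNA target prediction on 3'UTR sequences.
    Ships a self-contained RNA energetics core (hairpin folding and
    intermolecular duplex hybridization under a frozen nearest-neighbour
    model) and a synthetic study generator with a known truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
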