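Package: its2delimit
Title: Integrated ITS2 Species Delimitation from Sequence and Secondary
    Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Delimits fungal species from ITS2 (internal transcribed
    spacer 2) sequences by fusing an alignment-based substitution-model
    distance matrix and an alignment-free secondary-structure distance
    matrix into a DISTATIS compromise, building neighbor-joining and
    single-linkage trees with bootstrap support, delimiting clusters on
    ultrametric trees with single- and multiple-threshold generalized
    mixed Yule-coalescent (GMYC) models, and corroborating the partition
    with compensatory base change (CBC) counts and consensus secondary
    structure typing. Includes a simplified nearest-neighbour RNA folding
    model with an exact brute-force oracle, readers and writers for
    FASTA, Vienna dot-bracket and square PHYLIP distance formats, and a
    generator of ITS2-like synthetic families with planted CBCs for
    validation.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    seqinr,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
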