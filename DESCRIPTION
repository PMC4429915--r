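Package: heterochron
Title: Sequence Heterochrony Analysis on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of sequence heterochrony in ranked developmental
    event sequences on a rooted phylogeny. Implements the Parsimov
    event-pair edit cost between ranked sequences with ties and absences,
    a genetic-algorithm search for most-parsimonious ancestral sequences
    treating the whole sequence as a single complex character,
    majority-rule consensus trees with support values and mean-rank
    ancestral sequences, heterochrony-rate statistics aggregated by
    tissue, germ layer and body segment, a NEXUS dialect reader/writer,
    and a simulator of ranked-sequence evolution with known ground truth.
    Ships the rank table of 33 developmental events across seven
    crustacean species as a built-in dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
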