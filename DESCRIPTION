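Package: sirhet
Title: Detection of Short Inverted Repeat-Mediated Plastome Inversion
    Heteroplasmy from Short Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects structural heteroplasmy of circular organelle genomes
    caused by intramolecular homologous recombination between short inverted
    repeats (sIRs). Discovers sIR pairs in an assembled plastome by
    self-comparison, predicts the stem-loop structure of each arm, builds the
    alternative inverted-type reference, classifies discordant and
    soft-clipped paired-end reads against both references into eight
    support patterns, and estimates the minor isoform's frequency as
    supporting read pairs per mean depth over the recombination region.
    Ships a paired-end read simulator with a truth table so the whole
    pipeline can be validated against an independent oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
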