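Package: pairclone
Title: Clonal Family Inference for Paired Heavy and Light Chain B Cell
    Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers B cell receptor (BCR) clonal families from repertoires
    with heavy/light chain pairing information.  Single chain partitions are
    built by hierarchical agglomeration on inferred naive (unmutated
    ancestor) sequences and then refined into a joint partition using the
    pairing information from droplet barcodes.  Includes a method to
    disambiguate pairing information from overloaded droplets by clonal
    family voting, a method to approximately pair bulk (unpaired) sequences
    via a matched single cell sample, a from-scratch paired repertoire
    simulator with VDJ rearrangement, phylogenetic trees and somatic
    hypermutation, and precision/sensitivity metrics to benchmark all of it
    against simulation truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
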