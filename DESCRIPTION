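Package: inteinflow
Title: Intein Distributions as Markers of Gene Flow in Prokaryotic Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect intein insertions in host proteins, classify their
    symbiotic state (mini or large), and analyse their phylogenetic
    distribution as a marker of horizontal gene transfer. Includes a forward
    simulator of the intein homing cycle (invasion, endonuclease-mediated
    transfer biased toward close relatives, domain loss and precise deletion)
    on a species tree, position-specific scoring matrix construction and
    scanning, ortholog-based insertion extraction, a length-gap classifier for
    mini-inteins, Fitch parsimony presence-absence mapping, monophyly
    classification on unrooted trees, per-genus density profiles, and an
    exporter of mixed presence-absence plus sequence matrices for Bayesian
    clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
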