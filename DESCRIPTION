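Package: motudelim
Title: Ensemble Species Delimitation for DNA Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ensemble of single-locus species-delimitation methods for
    molecular operational taxonomic units (MOTUs): classical barcode-gap
    analysis (overall and pairwise, with fixed and fold-change threshold
    rules), automatic barcode gap discovery with recursive partitioning,
    the genealogical sorting index with permutation tests, Rosenberg's
    probability of reciprocal monophyly, Rodrigo's randomly-distinct
    clade test, species-delimitation summary statistics on trees, and
    single- and multiple-threshold general mixed Yule-coalescent (GMYC)
    model fits on ultrametric trees.  A consensus module assembles the
    per-method decisions into a support matrix and counts the minimum and
    maximum number of putative species implied under nested hypotheses.
    A multispecies-coalescent simulator generates alignments, trees and
    truth partitions so the whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    seqinr,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
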