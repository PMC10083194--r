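Package: attforge
Title: Discovery and Characterization of Large Serine Recombinase Attachment Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative-genomics discovery of large serine
    recombinases (LSRs) and their DNA attachment sites. Locates mobile
    genetic element insertion boundaries from genome pairs, reconstructs
    attB/attP attachment sites and their core dinucleotides, applies
    candidate quality-control filters, classifies target-site specificity
    by sequence clustering, builds and scans core-anchored nucleotide
    motifs with ROC evaluation, searches attachment sites against target
    genomes, calls genomic integration sites from donor-genome junction
    sequencing, computes enrichment statistics, and counts amplicon
    barcodes. Includes a synthetic-data generator so the full pipeline is
    testable against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    stats,
    utils,
    methods
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
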