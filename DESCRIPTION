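Package: chimeramap
Title: RNA-RNA Interactome and Structure Analysis from Proximity-Ligation Chimeric Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for proximity-ligation RNA interactome
    sequencing libraries in which two interacting RNA fragments are joined
    through a known linker oligo (RNA1-Linker-RNA2 chimeras). Parses raw
    paired-end reads (PCR-duplicate removal, sample demultiplexing by fixed
    barcodes, linker detection and read splitting), places fragments on a
    genome and assigns them to genes, repeats or novel loci, calls
    statistically enriched inter-RNA interactions (one-sided Fisher's exact
    test with Benjamini-Hochberg correction) and interaction sites, extracts
    intramolecular cut-and-ligated evidence of RNA structure (cut-density
    footprints, ligation contact maps, proximal site pairs), and computes
    sequence-level statistics (nearest-neighbour duplex hybridization energy
    against shuffled controls, conservation metaprofiles around ligation
    junctions, degree-distribution analysis of the interaction network).
    Ships a fully seeded synthetic-library simulator with ground truth so
    every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
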