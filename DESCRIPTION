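Package: mirssr
Title: Homology-Based miRNA Precursor Discovery and EST-SSR Marker Design
    for Transcriptome Assemblies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mining de novo transcriptome assemblies of non-model
    plants for conserved microRNAs and microsatellite (EST-SSR) markers.
    Implements a homology screen against known mature miRNAs (exact
    full-length matches, 200-nt flanking precursor windows, a six-frame
    open-reading-frame coding filter), an internal dynamic-programming
    minimum-free-energy RNA folder with dot-bracket output, the four
    classical hairpin precursor criteria together with AMFE and MFEI
    statistics, MISA-style microsatellite detection with motif-class
    canonicalization, and nearest-neighbor melting-temperature primer-pair
    design. A seeded synthetic-transcriptome generator plants hairpin
    precursors, criterion-violating decoys and SSR loci with a
    machine-readable truth table so the whole cascade is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    BiocGenerics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
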