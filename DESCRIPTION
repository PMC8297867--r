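Package: mitostruct
Title: Comparative Structural Analysis of Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative structure analysis of plant
    mitochondrial genomes: signed gene-order extraction from annotated
    genomes and double-cut-and-join (DCJ) rearrangement distances, detection
    of dispersed exact repeats (>= 50 bp), scanning and classification of
    short Bpu-like mobile elements under a bounded edit-distance model,
    detection of plastid-derived insertions (MTPTs) by local alignment,
    cataloguing of cis- and trans-spliced group II introns, and empirical
    C-to-U RNA-editing site calling from RNA/DNA read evidence with
    codon-level classification. Includes synthetic-genome generators with
    machine-readable ground truth so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml,
    pheatmap,
    grDevices,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
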