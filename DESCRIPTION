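Package: seqstab
Title: Detection and Removal of Evolutionary Instability Hotspots in Synthetic DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch detection and ranking of mutational hotspots in DNA sequences
    (simple-sequence repeats prone to polymerase slippage, long direct repeats
    mediating recombination deletions) and of epigenetic hotspots (methylation
    motifs scored with position-specific scoring matrices parsed from MEME
    minimal format), together with a two-pass constrained optimizer that
    removes the top-ranked hotspots while preserving amino-acid translation,
    locked regions, and windowed GC-content bounds, and optimizing host codon
    usage. Includes per-generation mutation-rate models calibrated on
    Escherichia coli data, a relative-instability score, seeded synthetic
    fixture generators with planted hotspots, and a batch command-line
    front-end for FASTA and GenBank input directories.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
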