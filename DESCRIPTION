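Package: editscope
Title: RNA-Editing-Based Discovery of RNA-Binding Protein Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies targets of an RNA-binding protein from RBP-ADARcd
    fusion experiments: calls A-to-I(G) editing sites from experiment versus
    control per-position nucleotide tallies with coverage and edit-fraction
    thresholds and replicate intersection, assigns edits to genes and
    transcript regions with metagene coordinates, extracts intronless windows
    around edits for k-mer motif enrichment, scores AU-rich elements in
    3'UTRs, and quantifies the RBP's effect on target-mRNA stability via
    median-of-ratios normalization, permutation-based differential expression,
    bootstrap/chi-square/Fisher stratification, and an intron-read nascent
    transcription control. Includes a seeded synthetic-data generator
    (genomes, annotations, edit-bearing pileups, count matrices) with planted
    ground truth so every stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
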