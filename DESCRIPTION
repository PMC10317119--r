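Package: plasmidpool
Title: Barcode-Free Validation of Pooled Nanopore Plasmid Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating plasmid sequences from pooled, barcode-free
    Oxford Nanopore sequencing runs. Reads are attributed to their source
    plasmid either by two-stage alignment against reference subsequences that
    are unique to a single plasmid (for dissimilar or marker-bearing pools) or
    by alignment against rotated copies of a shared reference linearized at
    clone-specific restriction sites (for clonal pools). Per-plasmid consensus
    sequences are then built by reference-guided pileup voting, never
    back-filled from the reference, and compared against the expected reference
    with a needle-style report, gap tallies and a 0-100 quality score. A
    nanopore-style read simulator (substitution/insertion/deletion errors with
    homopolymer-biased deletions, random or cut-site read starts, injectable
    variants and subclonal mixtures) makes the whole pipeline testable without
    a sequencer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
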