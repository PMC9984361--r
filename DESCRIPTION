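Package: clipsl
Title: Spliced-Leader and 5' Hairpin Detection in Long-Read cDNA Soft-Clips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of trans-splicing from long-read
    direct-cDNA alignments against a transcriptome. Mines 5' soft-clips
    for spliced-leader (SL) sequences with a semi-global aligner and a
    progressive 5'-trimming scan, calls endogenous 5' terminal hairpins
    with a reverse-complement stem test, measures library strand bias and
    positional base-quality profiles, and aggregates per-gene start-site
    tables with SL2/SL1 ratios and upstream-gene distances. Includes a
    synthetic direct-cDNA read simulator that reproduces the self-primed
    hairpin library artifact (antisense dominance, long low-quality 5'
    soft-clips) with per-read ground truth and oracle alignments, so the
    whole analysis runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Rsamtools,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
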