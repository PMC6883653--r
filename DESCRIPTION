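Package: readorient
Title: Reference-Free Orientation of Long cDNA Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the 5'-to-3' orientation of long cDNA sequencing reads
    (Oxford Nanopore, PacBio) without a genome or transcriptome reference at
    prediction time. Small neural classifiers -- a multilayer perceptron on
    normalized k-mer frequency vectors and a convolutional network on one-hot
    encoded 500-nt sliding windows -- are trained on sequences of known
    orientation (annotated transcripts, direct-RNA reads, or reads labeled by
    mapping). Includes cluster-level majority-vote correction of per-read
    predictions, extraction of sequence motifs from first-layer convolutional
    filters as position weight matrices written in MEME minimal format, and a
    synthetic transcriptome/read simulator with planted strand-asymmetric
    motifs and nanopore-like errors for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    S4Vectors,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
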