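Package: crisprIF
Title: Guide Design and Off-Target Prediction for Type I-F CRISPR-Cas
    Transcriptional Activation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design tools for CRISPR activation with the Pseudomonas
    aeruginosa type I-F Cascade. Scans promoter regions for 5'-CC PAM
    protospacers, classifies and ranks candidates by distance to the
    transcription start site, computes Csy3 stoichiometry for canonical and
    extended spacers, assembles multi-spacer CRISPR arrays and simulates
    Csy4 processing into mature crRNAs, models the positional
    mismatch-tolerance architecture of crRNA:DNA pairing (seed region,
    every-sixth-position flip-out, PAM-distal tolerance), and enumerates
    putative off-target sites for Cascade crRNAs and SpCas9 gRNAs with a
    promoter-proximity filter. Includes a seeded synthetic-genome generator
    with planted protospacers and off-target decoys for end-to-end
    validation.
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
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
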