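Package: regulogr
Title: Comparative Genomics Reconstruction of Bacterial Transcription-Factor Regulons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs regulons of homodimeric bacterial transcription
    factors by comparative genomics: palindromic motif discovery in promoter
    windows with an expectation-maximization model, position weight matrix
    scanning with a training-set-derived threshold, operon prediction from
    gene layout, bidirectional-best-hit orthology, a cross-genome consistency
    filter that removes genome-specific false positives, and assembly of
    orthologous regulons (regulogs) with descriptive statistics on binding
    site architecture.  Includes a seeded pangenome simulator that plants
    palindromic binding sites with known ground truth so that every stage of
    the pipeline is testable end to end.
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
    igraph,
    Matrix,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
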