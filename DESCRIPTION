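Package: tfcoop
Title: Transcription Factor Repertoire, Dimer Cooperation and Variation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Catalogs transcription factor (TF) genes from genome annotation,
    detects chromosomal TF clusters with a 250-kb nonoverlapping window and a
    family-sharing merge rule, transfers binding motifs (MEME format) by
    best-hit CDS homology, scans 500-bp promoters with an exact-null PWM
    scanner, infers candidate TF dimer cooperation from reverse-complement
    palindromes between motif consensus fragments, detects co-expression
    modules via soft-threshold adjacency and topological overlap, and computes
    per-region variation rates and NG86 Ka/Ks from variant data.  Includes a
    synthetic-data generator with machine-readable planted truth so every
    stage is testable end to end.
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
    vcfR,
    igraph,
    jsonlite,
    mclust,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
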