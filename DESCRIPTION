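Package: centrotrace
Title: Centromere Delineation and Centromeric Retrotransposon Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising transposon-dominated plant centromeres
    from binned CENH3 ChIP-seq tracks and repeat annotations: centromere
    interval calling from ChIP/Input enrichment, discovery and scoring of
    centromeric LTR retrotransposon (CR) families with a binned alignment
    score (S = L x N), the centromeric retrotransposon enrichment index
    (CRI/CLTRI), LTR insertion-time dating from 5'/3' terminal-repeat
    divergence, greedy identity clustering of centromeric LTRs, tandem-repeat
    detection and the tracing of centromeric satellite arrays back to LTR
    fragments. Includes a seeded banded local aligner, a gapless probe copy
    counter with a mismatch cap, and a synthetic-genome generator that plants
    element families, solo LTRs, satellite arrays and Poisson ChIP/Input
    counts with known truth so every step is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
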