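Package: ntmapr
Title: Junction-Based Mapping and Annotation of Natural Transposon Insertions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps insertions of natural transposons in assembled contigs and
    long reads by seeded local alignment of junction queries against a genome
    database and a transposon database, composition of split ("blue-red")
    alignments, insertion-site (TGN) and target site duplication (TSD)
    calling, junction-query extraction from contigs, IUPAC consensus motifs
    over TSD and flank sets, gene-level annotation of calls, and tabular
    export. Ships a synthetic planted-insertion genome simulator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
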