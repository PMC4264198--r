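Package: hybridASE
Title: Allele-Specific Expression and Imprinting Analysis for Reciprocal F1 Hybrids
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse reciprocal F1 hybrid transcriptomes from
    SNP-informative allelic read counts: pseudo-genome construction,
    allelic pileup counting from alignments, informative-SNP filtering,
    allele-specific expression (ASE) and parent-of-origin (imprinting)
    calling, a negative-binomial exact test for differential expression
    without replicates, FPKM and Shannon-entropy expression-breadth
    profiling, and hypergeometric gene-set enrichment. A synthetic-data
    generator with truth labels makes the whole chain testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
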