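Package: retromine
Title: Domain-Guided Mining and Structural Annotation of LTR Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies protein-coding retrotransposons in genome assemblies
    starting from conserved protein-domain matches rather than terminal
    repeats. A core-domain profile (reverse transcriptase by default) is
    scanned against all six reading frames of the assembly, matches are
    expanded into loci with 7.5 kb flanks, and each locus is structurally
    annotated with a full profile set: frameshift-split domain fragments are
    chained into single units, tandem elements are delineated by their core
    domains, long terminal repeat (LTR) pairs are detected by local
    alignment of the flanking windows, and each element receives a composite
    score and a parseable identifier. Redundancy is reduced by greedy
    identity/coverage clustering of the core-domain peptides. Includes a
    deterministic synthetic-genome generator with planted elements and truth
    tables so every stage is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
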