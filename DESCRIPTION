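Package: miRcore
Title: Stringent Core-Region Matching and Functional-Group Counting for
    Small RNA-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies microRNA expression from adapter-clipped small
    RNA-seq reads by exact matching of reads to end-trimmed core regions
    of mature miRNAs, collapsing miRNAs into user-defined functional
    groups with once-per-group counting. The end-trimmed core absorbs 5'
    and 3' isomiRs into their parent miRNA while rejecting polymorphic
    (internally substituted) isomiRs. Includes an accuracy metric that
    compares per-library total counts to the number of input reads in
    the canonical mature-miRNA length range, and a seeded simulator that
    generates references with duplicated-locus families plus read
    libraries with canonical, isomiR and background reads and full
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Sequencing, miRNA, Preprocessing, GeneExpression
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
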