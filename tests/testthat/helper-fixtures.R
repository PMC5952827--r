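# Small in-code fixtures shared across tests.

# A hand-built 4-miRNA reference: a duplicated-locus pair (identical
# sequences, shared accession prefix), a lettered paralog, and an
# unrelated family.
tinyReference <- function() {
    MiRNAReference(
        c("TGGAATGTAAAGAAGTATGTAT",
          "TGGAATGTAAAGAAGTATGTAT",
          "ACTGCATTATGAGCACTTAAAG",
          "CATTGCACTTGTCTCGGTCTGA"),
        ids = c("mmu-mir-9-2-5p", "mmu-mir-9-3-5p",
                "mmu-miR-9a-5p", "mmu-miR-25-3p"),
        accessions = c("MIMAT0000009_1", "MIMAT0000009_2",
                       "MIMAT0000099", "MIMAT0000652"))
}

writeTempFasta <- function(lines) {
    fa <- tempfile(fileext = ".fa")
    writeLines(lines, fa)
    fa
}

randomDNA <- function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Random small reference with unique cores, for property-style tests.
randomReference <- function(n = 6, lenRange = c(20, 24),
                            params = coreParams()) {
    seqs <- character(0)
    while (length(seqs) < n) {
        s <- randomDNA(sample(lenRange[1]:lenRange[2], 1))
        core <- extractCore(s, params)
        if (is.na(core))
            next
        clash <- any(vapply(seqs, function(e) grepl(core, e, fixed = TRUE) ||
                            grepl(extractCore(e, params), s, fixed = TRUE),
                            logical(1)))
        if (!clash)
            seqs <- c(seqs, s)
    }
    MiRNAReference(seqs, ids = sprintf("syn-miR-%d-5p", seq_len(n)),
                   accessions = sprintf("MIMAT%07d", seq_len(n)))
}
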