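# Shared low-level helpers.

BASES <- c("A", "C", "G", "T")

# Uppercase and map RNA U to DNA T so reference and reads share one alphabet.
normalizeSequences <- function(x) {
    chartr("u", "T", chartr("U", "T", toupper(x)))
}

# Deterministic C-locale lexicographic sort.
lexSort <- function(x) sort(x, method = "radix")

# Read sequences from FASTA or FASTQ (optionally gzipped) into a normalized
# character vector named by record id. Reading as BStringSet avoids the
# silent dropping of non-DNA letters, so RNA references survive intact.
readSequences <- function(path, format = c("fasta", "fastq")) {
    format <- match.arg(format)
    x <- tryCatch(
        Biostrings::readBStringSet(path, format = format),
        error = function(e) stop("malformed ", toupper(format), " file '",
                                 path, "': ", conditionMessage(e),
                                 call. = FALSE))
    out <- normalizeSequences(as.character(x))
    names(out) <- names(x)
    out
}
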