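#' Read a mature miRNA reference from miRBase-style FASTA
#'
#' Parses a mature-miRNA FASTA file (optionally gzip-compressed). The first
#' whitespace-delimited token of each header is taken as the miRNA name and
#' the second, when present, as the MIMAT-style accession; any further
#' description text is ignored. Sequences are normalized to uppercase DNA
#' (`U` is mapped to `T`).
#'
#' @param path path to the FASTA file.
#' @return A [MiRNAReference-class] with one entry per record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">mmu-miR-1a-3p MIMAT0000123", "UGGAAUGUAAAGAAGUAUGUAU"), fa)
#' ref <- readMatureFasta(fa)
#' accessions(ref)
#' @export
readMatureFasta <- function(path) {
    if (!file.exists(path))
        stop("reference FASTA not found: ", path, call. = FALSE)
    seqs <- readSequences(path, "fasta")
    if (length(seqs) == 0L)
        stop("empty reference: '", path, "' contains no FASTA records",
             call. = FALSE)
    toks <- strsplit(names(seqs), "[[:space:]]+")
    ids <- vapply(toks, `[`, character(1), 1L)
    acc <- vapply(toks, function(t)
        if (length(t) >= 2L) t[2L] else "", character(1))
    if (any(is.na(ids)) || any(!nzchar(ids))) {
        bad <- which(is.na(ids) | !nzchar(ids))[1L]
        stop("malformed FASTA: record ", bad, " has an empty header name",
             call. = FALSE)
    }
    if (anyDuplicated(ids))
        stop("duplicate miRNA identifiers in reference: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "),
             call. = FALSE)
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad))
        stop("malformed FASTA: record '", ids[which(bad)[1L]],
             "' contains characters outside {A,C,G,T,U,N}", call. = FALSE)
    MiRNAReference(unname(seqs), ids = ids, accessions = acc)
}

#' Write a mature miRNA reference as FASTA
#'
#' Headers carry the miRNA name and, when non-empty, the accession as the
#' second token, so [readMatureFasta()] round-trips the reference.
#'
#' @param ref a [MiRNAReference-class].
#' @param path output path (`.gz` suffix enables compression).
#' @return `path`, invisibly.
#' @export
writeReferenceFasta <- function(ref, path) {
    stopifnot(is(ref, "MiRNAReference"))
    x <- Biostrings::DNAStringSet(as.character(ref))
    acc <- mcols(ref)$accession
    names(x) <- ifelse(nzchar(acc), paste(names(ref), acc), names(ref))
    Biostrings::writeXStringSet(x, path, compress = grepl("\\.gz$", path))
    invisible(path)
}

#' Parse miRBase-style mature miRNA names into structural keys
#'
#' Applies the grammar
#' `<species>-<class>-<number><letter?>(-<locusIndex>)?(-<arm>)?` with the
#' class token case-folded (`mir`/`miR` are equivalent, `let` is kept
#' distinct). A trailing numeric token before the optional `5p`/`3p` arm is
#' interpreted as a locus index (e.g. `mmu-mir-9-2-5p`), which grouping by
#' name drops. Names that do not fit the grammar yield `parse_ok = FALSE`
#' with all structural fields empty; the function never errors.
#'
#' @param ids character vector of miRNA names.
#' @return A data.frame with columns `mirna_id`, `family_class` (`"miR"`,
#'   `"let"` or `""`), `core_number`, `letter`, `arm` (`"5p"`, `"3p"` or
#'   `""`), `locus_index` and logical `parse_ok`.
#' @examples
#' parseMiRNAName(c("mmu-miR-26a-5p", "mmu-mir-9-2-5p", "weird"))
#' @export
parseMiRNAName <- function(ids) {
    n <- length(ids)
    out <- data.frame(mirna_id = as.character(ids),
                      family_class = character(n), core_number = character(n),
                      letter = character(n), arm = character(n),
                      locus_index = character(n), parse_ok = logical(n),
                      stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
        tok <- strsplit(out$mirna_id[i], "-", fixed = TRUE)[[1L]]
        if (length(tok) < 3L || length(tok) > 5L || any(!nzchar(tok)))
            next
        cls <- switch(tolower(tok[2L]), mir = "miR", let = "let", NA_character_)
        if (is.na(cls))
            next
        m <- regmatches(tok[3L], regexec("^([0-9]+)([a-z]+)?$", tok[3L]))[[1L]]
        if (length(m) == 0L)
            next
        rest <- tok[-(1:3)]
        arm <- ""
        if (length(rest) && rest[length(rest)] %in% c("5p", "3p")) {
            arm <- rest[length(rest)]
            rest <- rest[-length(rest)]
        }
        locus <- ""
        if (length(rest) == 1L && grepl("^[0-9]+$", rest)) {
            locus <- rest
            rest <- character(0)
        }
        if (length(rest))
            next
        out$family_class[i] <- cls
        out$core_number[i] <- m[2L]
        out$letter[i] <- if (is.na(m[3L])) "" else m[3L]
        out$arm[i] <- arm
        out$locus_index[i] <- locus
        out$parse_ok[i] <- TRUE
    }
    out
}

#' Read and write functional-group tables as two-column TSV
#'
#' The on-disk format is a tab-separated file with columns `mirna_id` and
#' `group_id` and a single optional `#`-prefixed header line (written as
#' `#scheme=<scheme>` so that the round trip restores the scheme). Rows are
#' written in C-locale lexicographic order of `mirna_id`.
#'
#' @param table a [GroupTable-class].
#' @param path file path.
#' @return `writeGroupTable` returns `path` invisibly; `readGroupTable`
#'   returns a [GroupTable-class].
#' @examples
#' gt <- GroupTable("custom", c(a = "g1", b = "g1"))
#' f <- tempfile()
#' writeGroupTable(gt, f)
#' identical(groupAssignments(readGroupTable(f)), groupAssignments(gt))
#' @export
writeGroupTable <- function(table, path) {
    stopifnot(is(table, "GroupTable"))
    validObject(table)
    a <- table@assignments
    ord <- order(names(a), method = "radix")
    lines <- c(paste0("#scheme=", table@scheme),
               paste(names(a)[ord], unname(a)[ord], sep = "\t"))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeGroupTable
#' @export
readGroupTable <- function(path) {
    if (!file.exists(path))
        stop("group table not found: ", path, call. = FALSE)
    lines <- readLines(path)
    scheme <- "custom"
    if (length(lines) && startsWith(lines[1L], "#")) {
        m <- regmatches(lines[1L], regexec("^#scheme=(\\S+)", lines[1L]))[[1L]]
        if (length(m) == 2L)
            scheme <- m[2L]
        lines <- lines[-1L]
    }
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L)
        stop("group table '", path, "' contains no assignments", call. = FALSE)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad))
        stop("group table format error: row ", bad[1L],
             " does not have exactly 2 tab-separated columns", call. = FALSE)
    ids <- vapply(parts, `[`, character(1), 1L)
    grp <- vapply(parts, `[`, character(1), 2L)
    if (anyDuplicated(ids)) {
        dup <- unique(ids[duplicated(ids)])
        conflicting <- dup[vapply(dup, function(d)
            length(unique(grp[ids == d])) > 1L, logical(1))]
        if (length(conflicting))
            stop("group table conflict: miRNA(s) ",
                 paste(conflicting, collapse = ", "),
                 " listed with more than one group", call. = FALSE)
        stop("group table error: miRNA(s) ", paste(dup, collapse = ", "),
             " listed more than once", call. = FALSE)
    }
    GroupTable(scheme, stats::setNames(grp, ids))
}

#' Write a per-library count table (and optional stats sidecar) as TSV
#'
#' The count file has a `#group_id<TAB>count` header and one row per group
#' in C-locale lexicographic order, including zero-count groups so that
#' count matrices align across libraries. Integer policies print integer
#' counts; the `fractional` policy prints 6 decimal places. The optional
#' sidecar is a `key=value` text file with the library-level tallies.
#'
#' @param table a [CountTable-class].
#' @param path output TSV path.
#' @param statsPath optional path for the library-stats sidecar.
#' @param nRawReads,nInRange optional library-level tallies recorded in the
#'   sidecar: total raw reads, and reads in the 19-23 nt band.
#' @return `path`, invisibly.
#' @seealso [readCounts()]
#' @export
writeCounts <- function(table, path, statsPath = NULL,
                        nRawReads = NA_integer_, nInRange = NA_integer_) {
    stopifnot(is(table, "CountTable"))
    validObject(table)
    cnt <- table@counts[order(names(table@counts), method = "radix")]
    val <- if (table@policy == "fractional") sprintf("%.6f", cnt)
           else format(cnt, scientific = FALSE, trim = TRUE)
    writeLines(c("#group_id\tcount", paste(names(cnt), val, sep = "\t")), path)
    if (!is.null(statsPath)) {
        ratio <- if (is.na(nRawReads) || nRawReads == 0) NA_real_
                 else sum(cnt) / nRawReads
        writeLines(c(
            paste0("library_id=", table@libraryId),
            paste0("policy=", table@policy),
            paste0("n_reads_processed=", table@nReadsProcessed),
            paste0("n_reads_matched=", table@nReadsMatched),
            paste0("n_reads_ambiguous=", table@nReadsAmbiguous),
            paste0("total_count=", format(sum(cnt), scientific = FALSE)),
            paste0("n_raw_reads=", nRawReads),
            paste0("n_in_range_19_23=", nInRange),
            paste0("ratio_total_to_raw=",
                   format(ratio, scientific = FALSE))), statsPath)
    }
    invisible(path)
}

#' Read a count table written by [writeCounts()]
#'
#' @param path TSV path.
#' @return named numeric vector of counts.
#' @export
readCounts <- function(path) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L))
        stop("count table format error in '", path, "'", call. = FALSE)
    stats::setNames(as.numeric(vapply(parts, `[`, character(1), 2L)),
                    vapply(parts, `[`, character(1), 1L))
}

#' Read a library-stats sidecar written by [writeCounts()]
#'
#' @param path sidecar path.
#' @return one-row data.frame with columns `library_id`, `n_raw_reads`,
#'   `n_in_range_19_23`, `total_count` and `ratio_total_to_raw`.
#' @export
readLibraryStats <- function(path) {
    lines <- readLines(path)
    kv <- strsplit(lines[nzchar(lines)], "=", fixed = TRUE)
    vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                            vapply(kv, `[`, character(1), 1L))
    data.frame(library_id = vals[["library_id"]],
               n_raw_reads = as.numeric(vals[["n_raw_reads"]]),
               n_in_range_19_23 = as.numeric(vals[["n_in_range_19_23"]]),
               total_count = as.numeric(vals[["total_count"]]),
               ratio_total_to_raw = as.numeric(vals[["ratio_total_to_raw"]]),
               stringsAsFactors = FALSE)
}
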