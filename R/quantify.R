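#' Quantify a read library against a core index
#'
#' Streams an adapter-clipped read library through the exact core matcher
#' and accumulates per-functional-group counts. Each read contributes at
#' most once to any single group. When a read matches more than one group
#' the `policy` decides the cross-group behaviour:
#' \describe{
#'   \item{`all_groups`}{(default) add 1 to every matched group — the
#'     literal once-per-group reading; a read matching k groups adds k in
#'     total.}
#'   \item{`discard_ambiguous`}{count the read only when it matches exactly
#'     one group.}
#'   \item{`fractional`}{add 1/k to each of the k matched groups.}
#' }
#' Identical reads are deduplicated internally and matched once, which is
#' observationally equivalent to per-read matching; the result is invariant
#' to read order. Zero-count groups are retained so count matrices align
#' across libraries.
#'
#' @param reads a FASTQ path (`.gz` allowed), a `DNAStringSet`/`BStringSet`,
#'   or a character vector of read sequences.
#' @param index a [CoreIndex-class].
#' @param policy counting policy, see above.
#' @param libraryId label recorded in the result.
#' @return A [CountTable-class] dense over the index's group universe.
#' @examples
#' ref <- MiRNAReference(c("TGGAATGTAAAGAAGTATGTAT"), ids = "mmu-miR-1a-3p")
#' idx <- buildCoreIndex(ref, buildGroups(ref, "none"))
#' ct <- quantifyLibrary(c("TGGAATGTAAAGAAGTATGTAT",
#'                         "GAATGTAAAGAAGTATGTATCC"), idx)
#' groupCounts(ct)
#' @export
quantifyLibrary <- function(reads, index,
                            policy = c("all_groups", "discard_ambiguous",
                                       "fractional"),
                            libraryId = "library") {
    stopifnot(is(index, "CoreIndex"))
    policy <- match.arg(policy)
    seqs <- readsAsCharacter(reads)
    counts <- stats::setNames(numeric(length(index@groupIds)), index@groupIds)
    nProc <- length(seqs)
    if (nProc == 0L) {
        warning("empty library '", libraryId, "': returning all-zero counts",
                call. = FALSE)
        return(new("CountTable", libraryId = libraryId, counts = counts,
                   nReadsProcessed = 0L, nReadsMatched = 0L,
                   nReadsAmbiguous = 0L, policy = policy))
    }
    uni <- unique(seqs)
    mult <- tabulate(match(seqs, uni), nbins = length(uni))
    matches <- lapply(uni, matchRead, index = index)
    k <- lengths(matches)
    nMatched <- sum(mult[k >= 1L])
    nAmbig <- sum(mult[k >= 2L])
    use <- switch(policy,
        all_groups = k >= 1L,
        discard_ambiguous = k == 1L,
        fractional = k >= 1L)
    if (any(use)) {
        g <- unlist(matches[use], use.names = FALSE)
        w <- rep(mult[use], k[use])
        if (policy == "fractional")
            w <- w / rep(k[use], k[use])
        agg <- rowsum(w, g)
        counts[rownames(agg)] <- counts[rownames(agg)] + agg[, 1L]
    }
    new("CountTable", libraryId = libraryId, counts = counts,
        nReadsProcessed = nProc, nReadsMatched = as.integer(nMatched),
        nReadsAmbiguous = as.integer(nAmbig), policy = policy)
}

# Accept a FASTQ path, an XStringSet, or a character vector of sequences,
# and return normalized sequences.
readsAsCharacter <- function(reads) {
    if (is.character(reads) && length(reads) == 1L && file.exists(reads))
        readSequences(reads, "fastq")
    else if (methods::is(reads, "XStringSet"))
        normalizeSequences(as.character(reads))
    else if (is.character(reads))
        normalizeSequences(reads)
    else
        stop("'reads' must be a FASTQ path, an XStringSet or a character ",
             "vector of sequences", call. = FALSE)
}

#' Library-level statistics for one quantified library
#'
#' Combines a [CountTable-class] with its source reads into the per-library
#' summary used by the ratio and accuracy evaluations: the number of raw
#' reads, the number in the canonical mature-miRNA length band (19-23 nt,
#' the estimate of miRNA input reads), the total group count, and the
#' ratio of total count to raw reads.
#'
#' @param table a [CountTable-class].
#' @param reads the library the table was computed from (path, XStringSet
#'   or character vector).
#' @param minLen,maxLen inclusive bounds of the miRNA length band.
#' @return one-row data.frame with columns `library_id`, `n_raw_reads`,
#'   `n_in_range_19_23`, `total_count`, `ratio_total_to_raw` (NA when the
#'   library is empty).
#' @export
libraryStats <- function(table, reads, minLen = 19, maxLen = 23) {
    stopifnot(is(table, "CountTable"))
    seqs <- readsAsCharacter(reads)
    nRaw <- length(seqs)
    data.frame(
        library_id = table@libraryId,
        n_raw_reads = nRaw,
        n_in_range_19_23 = countReadsInLengthRange(seqs, minLen, maxLen),
        total_count = totalCount(table),
        ratio_total_to_raw = if (nRaw == 0L) NA_real_
                             else totalCount(table) / nRaw,
        stringsAsFactors = FALSE)
}
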