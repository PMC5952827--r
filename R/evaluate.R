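#' Count reads in an inclusive length range
#'
#' The number of adapter-clipped reads between 19 and 23 nt (inclusive)
#' estimates the number of reads of miRNA origin in a library: the large
#' majority of mature miRNAs fall in this length band, so after adapter
#' clipping the insert length is the discriminating signal.
#'
#' @param reads FASTQ path (`.gz` allowed), XStringSet or character vector.
#' @param minLen,maxLen inclusive bounds in nt.
#' @return integer count.
#' @examples
#' countReadsInLengthRange(c("ACGTACGTACGTACGTAC",      # 18 nt
#'                           "ACGTACGTACGTACGTACG",     # 19 nt
#'                           "ACGTACGTACGTACGTACGTACG", # 23 nt
#'                           "ACGTACGTACGTACGTACGTACGT"))
#' @export
countReadsInLengthRange <- function(reads, minLen = 19, maxLen = 23) {
    seqs <- readsAsCharacter(reads)
    w <- nchar(seqs)
    sum(w >= minLen & w <= maxLen)
}

#' Fraction of reference entries in a length range
#'
#' Computes the fraction of mature miRNA records (or of unique mature
#' sequences) whose length falls in the given inclusive band. Used to
#' check a reference against the expectation that most mature miRNAs are
#' 19-23 nt long.
#'
#' @param mirnas a [MiRNAReference-class].
#' @param minLen,maxLen inclusive bounds in nt.
#' @param uniqueSequences if `TRUE`, compute the fraction over unique
#'   mature sequences instead of over records.
#' @return numeric fraction in `[0, 1]`.
#' @export
lengthRangeFraction <- function(mirnas, minLen = 19, maxLen = 23,
                                uniqueSequences = FALSE) {
    stopifnot(is(mirnas, "MiRNAReference"))
    s <- as.character(mirnas)
    if (uniqueSequences)
        s <- unique(s)
    w <- nchar(s)
    mean(w >= minLen & w <= maxLen)
}

#' Mean squared error between estimated miRNA input reads and total counts
#'
#' The accuracy metric for a quantification method: for each library, the
#' squared difference between the estimated number of miRNA input reads
#' (e.g. reads 19-23 nt long) and the method's total output count; the
#' method-level score is the mean of these squared errors, with a standard
#' error of the mean computed from the sample (n - 1) standard deviation.
#' Squared errors are computed on raw counts, not normalized values.
#'
#' @param estimates numeric vector, per-library estimated miRNA input reads.
#' @param totals numeric vector, per-library total counts, paired with
#'   `estimates` by position.
#' @param methodLabel label for the method being scored.
#' @return An [EvalResult-class]. `sem` is `NA` when only one library is
#'   supplied.
#' @examples
#' mseSem(c(100, 200), c(90, 210))  # MSE 100, SEM 0
#' @export
mseSem <- function(estimates, totals, methodLabel = "method") {
    if (length(estimates) == 0L)
        stop("no libraries supplied", call. = FALSE)
    if (length(estimates) != length(totals))
        stop("pairing error: 'estimates' and 'totals' have different lengths",
             call. = FALSE)
    sq <- (as.numeric(estimates) - as.numeric(totals))^2
    n <- length(sq)
    new("EvalResult", methodLabel = methodLabel, squaredErrors = sq,
        mse = mean(sq),
        sem = if (n > 1L) stats::sd(sq) / sqrt(n) else NA_real_,
        nLibraries = n)
}

#' Per-library ratio of total count to raw reads
#'
#' Tabulates, for a set of quantified libraries, the ratio of the method's
#' total count to the number of raw input reads — the quantity plotted to
#' compare how different counting policies inflate or deflate library
#' totals (a ratio of 0.8 means the total count was 0.8 times the raw
#' reads; ratios above 1 indicate double counting).
#'
#' @param stats data.frame of per-library rows as produced by
#'   [libraryStats()] (or read back with [readLibraryStats()]), requiring
#'   columns `library_id`, `n_raw_reads` and `total_count`.
#' @return data.frame with columns `library_id`, `n_raw_reads`,
#'   `total_count` and `ratio`, sorted by `library_id`; the ratio is `NA`
#'   for libraries with zero raw reads.
#' @export
ratioTable <- function(stats) {
    stopifnot(is.data.frame(stats), nrow(stats) > 0L,
              all(c("library_id", "n_raw_reads", "total_count") %in%
                  colnames(stats)))
    out <- data.frame(
        library_id = stats$library_id,
        n_raw_reads = stats$n_raw_reads,
        total_count = stats$total_count,
        ratio = ifelse(stats$n_raw_reads == 0, NA_real_,
                       stats$total_count / stats$n_raw_reads),
        stringsAsFactors = FALSE)
    out[order(out$library_id, method = "radix"), , drop = FALSE]
}
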