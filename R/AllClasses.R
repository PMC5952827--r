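#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importClassesFrom Biostrings XStringSet BStringSet DNAStringSet
NULL

#' Mature miRNA reference set
#'
#' A [Biostrings::DNAStringSet] holding normalized mature miRNA sequences
#' (uppercase DNA, U mapped to T on ingest), with the miRNA name as the
#' element name and the miRBase-style accession (possibly carrying an
#' underscore suffix such as `MIMAT0000001_2` for individualized or
#' duplicated-locus entries) in `mcols(x)$accession`.
#'
#' @slot .Data inherited from `DNAStringSet`.
#' @seealso [readMatureFasta()], [MiRNAReference()]
#' @export
setClass("MiRNAReference", contains = "DNAStringSet")

setValidity("MiRNAReference", function(object) {
    msg <- character(0)
    if (length(object) == 0L)
        msg <- c(msg, "reference must contain at least one miRNA")
    nm <- names(object)
    if (is.null(nm) || any(is.na(nm)) || any(!nzchar(nm)))
        msg <- c(msg, "every miRNA must have a non-empty name")
    else if (anyDuplicated(nm))
        msg <- c(msg, paste0("duplicate miRNA identifiers: ",
                             paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    mc <- mcols(object)
    if (is.null(mc) || !("accession" %in% colnames(mc)))
        msg <- c(msg, "mcols must contain an 'accession' column")
    sq <- as.character(object)
    if (any(!nzchar(sq)))
        msg <- c(msg, "sequences must be non-empty")
    bad <- grepl("[^ACGTN]", sq)
    if (any(bad))
        msg <- c(msg, paste0("sequences outside the {A,C,G,T,N} alphabet: ",
                             paste(nm[bad], collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct a mature miRNA reference
#'
#' @param sequences character vector or `DNAStringSet` of mature sequences
#'   (RNA `U` is mapped to `T`, lowercase is uppercased).
#' @param ids character vector of unique miRNA names. Defaults to
#'   `names(sequences)`.
#' @param accessions character vector of MIMAT-style accessions; `""` where
#'   absent.
#' @return A [MiRNAReference-class] object.
#' @examples
#' ref <- MiRNAReference(c("UGGAAUGUAAAGAAGUAUGUAU"),
#'                       ids = "mmu-miR-1a-3p",
#'                       accessions = "MIMAT0000123")
#' mirnaIds(ref)
#' @export
MiRNAReference <- function(sequences, ids = names(sequences),
                           accessions = character(length(sequences))) {
    seqs <- normalizeSequences(as.character(sequences))
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    mcols(x) <- DataFrame(accession = as.character(accessions))
    new("MiRNAReference", x)
}

#' Core-region extraction and read-matching parameters
#'
#' @slot trim5 integer, bases trimmed from the 5' end of each mature miRNA
#'   when forming its core (default 2).
#' @slot trim3 integer, bases trimmed from the 3' end (default 2).
#' @slot minCoreLen integer, minimum admissible core length in nt; miRNAs
#'   whose trimmed core would be shorter are excluded from the index
#'   (default 16).
#' @slot minReadLen,maxReadLen integer read-length gates: reads outside
#'   `[minReadLen, maxReadLen]` never match (defaults 16 and 30).
#' @export
setClass("CoreParams",
    representation(trim5 = "integer", trim3 = "integer",
                   minCoreLen = "integer",
                   minReadLen = "integer", maxReadLen = "integer"))

setValidity("CoreParams", function(object) {
    msg <- character(0)
    for (s in c("trim5", "trim3", "minCoreLen", "minReadLen", "maxReadLen")) {
        v <- slot(object, s)
        if (length(v) != 1L || is.na(v) || v < 0L)
            msg <- c(msg, paste0("'", s, "' must be a single non-negative integer"))
    }
    if (!length(msg) && object@minReadLen > object@maxReadLen)
        msg <- c(msg, "minReadLen must not exceed maxReadLen")
    if (length(msg)) msg else TRUE
})

#' @rdname CoreParams-class
#' @param trim5,trim3,minCoreLen,minReadLen,maxReadLen see slot descriptions.
#' @return A `CoreParams` object.
#' @examples
#' coreParams()
#' coreParams(trim5 = 3, trim3 = 3)
#' @export
coreParams <- function(trim5 = 2, trim3 = 2, minCoreLen = 16,
                       minReadLen = 16, maxReadLen = 30) {
    new("CoreParams",
        trim5 = as.integer(trim5), trim3 = as.integer(trim3),
        minCoreLen = as.integer(minCoreLen),
        minReadLen = as.integer(minReadLen),
        maxReadLen = as.integer(maxReadLen))
}

#' Functional-group assignment table
#'
#' Total mapping from miRNA identifier to functional-group identifier under
#' one of the collapsing schemes: `"none"` (each miRNA its own group),
#' `"mimat"` (same accession before the first underscore), `"name"` (same
#' family class, core number, letter and 5p/3p arm), or `"custom"` for
#' user-supplied tables.
#'
#' @slot scheme character scalar.
#' @slot assignments named character vector; names are miRNA ids, values
#'   are group ids.
#' @seealso [buildGroups()], [readGroupTable()]
#' @export
setClass("GroupTable",
    representation(scheme = "character", assignments = "character"))

setValidity("GroupTable", function(object) {
    msg <- character(0)
    if (length(object@scheme) != 1L || !nzchar(object@scheme))
        msg <- c(msg, "scheme must be a single non-empty string")
    a <- object@assignments
    if (length(a) == 0L)
        msg <- c(msg, "assignments must be non-empty")
    nm <- names(a)
    if (is.null(nm) || any(!nzchar(nm)))
        msg <- c(msg, "every assignment must be named by a miRNA id")
    else if (anyDuplicated(nm))
        msg <- c(msg, "each miRNA may appear only once")
    if (any(is.na(a)) || any(!nzchar(a)))
        msg <- c(msg, "group ids must be non-empty strings")
    if (length(msg)) msg else TRUE
})

GroupTable <- function(scheme, assignments) {
    new("GroupTable", scheme = scheme, assignments = assignments)
}

#' Exact-lookup index from core sequences to functional groups
#'
#' Maps every admissible end-trimmed core sequence to the set of group ids
#' whose miRNAs carry that core. Cores containing `N` are kept in the entry
#' list for reporting but can never be matched by a read (`N` is not equal
#' to any base).
#'
#' @slot params the [CoreParams-class] used to extract the cores.
#' @slot entries named list, core sequence -> character vector of group ids.
#' @slot provenance named list, core sequence -> contributing miRNA ids.
#' @slot lookup environment used for O(1) exact lookup (N-free cores only).
#' @slot coreLengths sorted integer vector of distinct core lengths.
#' @slot groupIds full group universe (dense count output covers all of
#'   these, including groups whose miRNAs yielded no admissible core).
#' @slot nExcluded number of miRNAs excluded because their core was shorter
#'   than `minCoreLen`.
#' @seealso [buildCoreIndex()], [matchRead()]
#' @export
setClass("CoreIndex",
    representation(params = "CoreParams", entries = "list",
                   provenance = "list", lookup = "environment",
                   coreLengths = "integer", groupIds = "character",
                   nExcluded = "integer"))

setValidity("CoreIndex", function(object) {
    msg <- character(0)
    keys <- names(object@entries)
    if (length(object@entries) == 0L)
        msg <- c(msg, "index must contain at least one core")
    if (any(nchar(keys) < object@params@minCoreLen))
        msg <- c(msg, "all core keys must be at least minCoreLen long")
    if (any(lengths(object@entries) == 0L))
        msg <- c(msg, "every core must map to at least one group")
    if (length(msg)) msg else TRUE
})

#' Per-library functional-group count table
#'
#' @slot libraryId character scalar.
#' @slot counts named numeric vector, dense over the group universe
#'   (zero-count groups included); integer-valued except under the
#'   `fractional` policy.
#' @slot nReadsProcessed,nReadsMatched,nReadsAmbiguous integer tallies;
#'   a read is matched if it hits at least one group and ambiguous if it
#'   hits at least two.
#' @slot policy one of `"all_groups"`, `"discard_ambiguous"`, `"fractional"`.
#' @seealso [quantifyLibrary()], [writeCounts()]
#' @export
setClass("CountTable",
    representation(libraryId = "character", counts = "numeric",
                   nReadsProcessed = "integer", nReadsMatched = "integer",
                   nReadsAmbiguous = "integer", policy = "character"))

setValidity("CountTable", function(object) {
    msg <- character(0)
    if (any(object@counts < 0))
        msg <- c(msg, "counts must be non-negative")
    if (is.null(names(object@counts)))
        msg <- c(msg, "counts must be named by group id")
    if (object@nReadsMatched > object@nReadsProcessed)
        msg <- c(msg, "matched reads cannot exceed processed reads")
    if (object@nReadsAmbiguous > object@nReadsMatched)
        msg <- c(msg, "ambiguous reads cannot exceed matched reads")
    if (!object@policy %in% c("all_groups", "discard_ambiguous", "fractional"))
        msg <- c(msg, "unknown counting policy")
    if (length(msg)) msg else TRUE
})

#' Accuracy-metric result
#'
#' Mean squared error between per-library estimated miRNA input reads and
#' per-library total output counts, with the standard error of the mean of
#' the squared errors (sample standard deviation, n - 1).
#'
#' @slot methodLabel character scalar.
#' @slot squaredErrors numeric vector of per-library squared errors.
#' @slot mse mean of `squaredErrors`.
#' @slot sem `sd(squaredErrors)/sqrt(n)`; `NA` when only one library.
#' @slot nLibraries integer.
#' @seealso [mseSem()]
#' @export
setClass("EvalResult",
    representation(methodLabel = "character", squaredErrors = "numeric",
                   mse = "numeric", sem = "numeric", nLibraries = "integer"))

#' Simulation parameters
#'
#' Controls the synthetic mature-miRNA reference and read-library generator.
#' Defaults emulate the structure of real small RNA-seq data: mature lengths
#' in 19-23 nt (the canonical mature-miRNA length band), right-skewed
#' per-group abundances (log-normal), 3' isomiRs as the most common isomiR
#' class, and a background of non-miRNA fragments spanning 16-30 nt.
#'
#' @slot nFamilies number of miRNA functional groups (families) to simulate.
#' @slot pDuplicateLocus probability that a family has a second locus with
#'   an identical mature sequence (name gains a locus index, accession an
#'   underscore suffix).
#' @slot mirnaLenRange integer length-2 vector, inclusive range of mature
#'   miRNA lengths.
#' @slot abundanceMeanlog,abundanceSdlog log-normal abundance parameters on
#'   the natural-log scale.
#' @slot frac5p,frac3p,fracPolymorphic per-read probabilities of the 5'
#'   isomiR, 3' isomiR and polymorphic isomiR classes; the remainder is
#'   canonical.
#' @slot maxEndShift maximum isomiR end shift in nt.
#' @slot nMirnaReads,nBackgroundReads reads of miRNA origin / background
#'   fragments per library.
#' @slot seqErrorRate per-base substitution error probability.
#' @slot seed integer RNG seed.
#' @seealso [simParams()], [simulateReference()], [simulateReads()]
#' @export
setClass("SimParams",
    representation(nFamilies = "integer", pDuplicateLocus = "numeric",
                   mirnaLenRange = "integer",
                   abundanceMeanlog = "numeric", abundanceSdlog = "numeric",
                   frac5p = "numeric", frac3p = "numeric",
                   fracPolymorphic = "numeric",
                   maxEndShift = "integer",
                   nMirnaReads = "integer", nBackgroundReads = "integer",
                   seqErrorRate = "numeric", seed = "integer"))

setValidity("SimParams", function(object) {
    msg <- character(0)
    fr <- c(object@frac5p, object@frac3p, object@fracPolymorphic)
    if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
        msg <- c(msg, "class fractions must lie in [0,1] and sum to at most 1")
    p <- object@pDuplicateLocus
    if (p < 0 || p > 1)
        msg <- c(msg, "pDuplicateLocus must lie in [0,1]")
    lr <- object@mirnaLenRange
    if (length(lr) != 2L || lr[1] > lr[2] || lr[1] < 16L || lr[2] > 30L)
        msg <- c(msg, "mirnaLenRange must be an increasing pair within [16,30]")
    if (object@seqErrorRate < 0 || object@seqErrorRate > 1)
        msg <- c(msg, "seqErrorRate must lie in [0,1]")
    if (object@nFamilies < 1L)
        msg <- c(msg, "nFamilies must be positive")
    if (length(msg)) msg else TRUE
})

#' Ground truth for a simulated read library
#'
#' @slot perRead data.frame with one row per simulated read: `read_id`,
#'   `mirna_id` (NA for background), `group_id` (truth family or
#'   `"background"`), `class` (canonical/iso5p/iso3p/polymorphic/background)
#'   and `countable` (logical: canonical reads plus end-shift isomiRs whose
#'   deletions fit within the declared trims, from miRNAs with an admissible
#'   core, undamaged by sequencing error inside the core).
#' @slot countableCounts named integer vector, countable reads per truth
#'   family (dense over families).
#' @slot familyMembers named list, truth family -> member miRNA ids.
#' @seealso [simulateReads()], [trueGroupCounts()]
#' @export
setClass("SimTruth",
    representation(perRead = "data.frame", countableCounts = "integer",
                   familyMembers = "list"))
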