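#' @rdname MiRNAReference-class
#' @param x a `MiRNAReference`.
#' @export
setGeneric("mirnaIds", function(x) standardGeneric("mirnaIds"))

#' @rdname MiRNAReference-class
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' @rdname GroupTable-class
#' @param x a `GroupTable`.
#' @export
setGeneric("groupScheme", function(x) standardGeneric("groupScheme"))

#' @rdname GroupTable-class
#' @export
setGeneric("groupAssignments", function(x) standardGeneric("groupAssignments"))

#' @rdname GroupTable-class
#' @export
setGeneric("groupIds", function(x) standardGeneric("groupIds"))

#' @rdname CountTable-class
#' @param x a `CountTable`.
#' @export
setGeneric("groupCounts", function(x) standardGeneric("groupCounts"))

#' @rdname CountTable-class
#' @export
setGeneric("totalCount", function(x) standardGeneric("totalCount"))

#' @rdname CoreIndex-class
#' @param x a `CoreIndex`.
#' @export
setGeneric("coreSequences", function(x) standardGeneric("coreSequences"))

#' Number of cores shared by more than one group
#'
#' Ambiguity diagnostic for a [CoreIndex-class]: cores carried by miRNAs
#' assigned to two or more distinct functional groups.
#' @param x a `CoreIndex`.
#' @return integer scalar.
#' @export
setGeneric("ambiguousCoreCount", function(x) standardGeneric("ambiguousCoreCount"))

setMethod("mirnaIds", "MiRNAReference", function(x) names(x))

setMethod("accessions", "MiRNAReference", function(x) {
    a <- mcols(x)$accession
    names(a) <- names(x)
    a
})

setMethod("groupScheme", "GroupTable", function(x) x@scheme)

setMethod("groupAssignments", "GroupTable", function(x) x@assignments)

setMethod("groupIds", "GroupTable",
          function(x) sort(unique(unname(x@assignments)), method = "radix"))

setMethod("groupCounts", "CountTable", function(x) x@counts)

setMethod("totalCount", "CountTable", function(x) sum(x@counts))

setMethod("coreSequences", "CoreIndex", function(x) names(x@entries))

setMethod("ambiguousCoreCount", "CoreIndex",
          function(x) sum(lengths(x@entries) > 1L))

setMethod("show", "MiRNAReference", function(object) {
    cat("MiRNAReference with", length(object), "mature miRNAs\n")
    cat("  lengths:", paste(range(Biostrings::width(object)), collapse = "-"),
        "nt\n")
    n <- min(3L, length(object))
    for (i in seq_len(n))
        cat("  ", names(object)[i], " (", mcols(object)$accession[i], ") ",
            as.character(object[[i]]), "\n", sep = "")
    if (length(object) > n) cat("  ...\n")
})

setMethod("show", "CoreParams", function(object) {
    cat("CoreParams: trim5=", object@trim5, " trim3=", object@trim3,
        " minCoreLen=", object@minCoreLen,
        " readLen=[", object@minReadLen, ",", object@maxReadLen, "]\n",
        sep = "")
})

setMethod("show", "GroupTable", function(object) {
    cat("GroupTable (scheme: ", object@scheme, ")\n", sep = "")
    cat("  ", length(object@assignments), " miRNAs in ",
        length(unique(object@assignments)), " functional groups\n", sep = "")
})

setMethod("show", "CoreIndex", function(object) {
    cat("CoreIndex with", length(object@entries), "distinct cores over",
        length(object@groupIds), "groups\n")
    cat("  core lengths:", paste(object@coreLengths, collapse = ", "), "nt\n")
    cat("  cores shared by >1 group:", ambiguousCoreCount(object), "\n")
    if (object@nExcluded > 0L)
        cat("  miRNAs excluded (core < minCoreLen):", object@nExcluded, "\n")
})

setMethod("show", "CountTable", function(object) {
    cat("CountTable for library '", object@libraryId, "' (policy: ",
        object@policy, ")\n", sep = "")
    cat("  reads processed: ", object@nReadsProcessed,
        ", matched: ", object@nReadsMatched,
        ", ambiguous: ", object@nReadsAmbiguous, "\n", sep = "")
    cat("  total count over ", length(object@counts), " groups: ",
        format(totalCount(object)), "\n", sep = "")
})

setMethod("show", "EvalResult", function(object) {
    cat("EvalResult for '", object@methodLabel, "' over ",
        object@nLibraries, " libraries\n", sep = "")
    cat("  MSE: ", format(object@mse), "  SEM: ", format(object@sem),
        "\n", sep = "")
})

setMethod("show", "SimParams", function(object) {
    cat("SimParams:", object@nFamilies, "families, pDuplicateLocus =",
        object@pDuplicateLocus, "\n")
    cat("  mature lengths", paste(object@mirnaLenRange, collapse = "-"),
        "nt; abundance ~ logN(", object@abundanceMeanlog, ",",
        object@abundanceSdlog, ")\n")
    cat("  class fractions: 5p", object@frac5p, "| 3p", object@frac3p,
        "| polymorphic", object@fracPolymorphic, "| maxEndShift",
        object@maxEndShift, "\n")
    cat("  reads/library:", object@nMirnaReads, "miRNA +",
        object@nBackgroundReads, "background; error rate",
        object@seqErrorRate, "; seed", object@seed, "\n")
})

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth for", nrow(object@perRead), "reads over",
        length(object@countableCounts), "families\n")
    cat("  countable reads:", sum(object@countableCounts), "\n")
})
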