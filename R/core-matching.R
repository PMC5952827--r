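#' Extract the end-trimmed core region of a mature miRNA
#'
#' The core is the interior of the sequence after removing `trim5` bases
#' from the 5' end and `trim3` bases from the 3' end. It is the exact-match
#' anchor used for read matching: trimming makes the match tolerant to
#' end variation (5'/3' isomiRs, untemplated additions) while remaining
#' exact in the interior. Cores shorter than `minCoreLen` are rejected.
#'
#' @param sequence character vector of normalized sequences.
#' @param params a [CoreParams-class].
#' @return character vector of cores; `NA` where the trimmed core would be
#'   shorter than `minCoreLen`.
#' @examples
#' extractCore("ACGTACGTACGTACGTACGTAC", coreParams(trim5 = 2, trim3 = 2))
#' @export
extractCore <- function(sequence, params = coreParams()) {
    stopifnot(is(params, "CoreParams"))
    n <- nchar(sequence)
    core <- substr(sequence, params@trim5 + 1L, n - params@trim3)
    core[nchar(core) < params@minCoreLen | n < params@trim5 + params@trim3] <-
        NA_character_
    core
}

#' Build an exact-lookup core index
#'
#' Extracts the core of every miRNA and maps each distinct core sequence to
#' the set of functional groups whose members carry it (set semantics:
#' identical miRNAs in one group contribute a single entry). miRNAs whose
#' core falls below `minCoreLen` are excluded with a warning. Cores
#' containing `N` are recorded but are never matchable — `N` is treated as
#' equal to no base, which is the conservative choice under ambiguity.
#'
#' @param mirnas a [MiRNAReference-class].
#' @param groups a [GroupTable-class] covering `mirnas`.
#' @param params a [CoreParams-class].
#' @return A [CoreIndex-class].
#' @examples
#' ref <- MiRNAReference(c("TGGAATGTAAAGAAGTATGTAT", "CATTGCACTTGTCTCGGTCTGA"),
#'                       ids = c("mmu-miR-1a-3p", "mmu-miR-25-3p"))
#' idx <- buildCoreIndex(ref, buildGroups(ref, "none"))
#' idx
#' @export
buildCoreIndex <- function(mirnas, groups, params = coreParams()) {
    stopifnot(is(mirnas, "MiRNAReference"), is(groups, "GroupTable"),
              is(params, "CoreParams"))
    assign <- groups@assignments
    ids <- mirnaIds(mirnas)
    missing <- setdiff(ids, names(assign))
    if (length(missing))
        stop("group table does not cover the reference: missing ",
             paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    cores <- extractCore(as.character(mirnas), params)
    keep <- !is.na(cores)
    if (!any(keep))
        stop("empty index: no miRNA yields a core of at least ",
             params@minCoreLen, " nt under trim5=", params@trim5,
             ", trim3=", params@trim3, call. = FALSE)
    if (any(!keep))
        warning(sum(!keep), " miRNA(s) excluded from the index: core ",
                "shorter than ", params@minCoreLen, " nt", call. = FALSE)
    ids <- ids[keep]
    cores <- cores[keep]
    grp <- unname(assign[ids])
    entries <- lapply(split(grp, cores), function(g) lexSort(unique(g)))
    provenance <- lapply(split(ids, cores), function(m) lexSort(unique(m)))
    lookup <- new.env(parent = emptyenv(), size = length(entries))
    for (core in names(entries))
        if (!grepl("N", core, fixed = TRUE))
            assign(core, entries[[core]], envir = lookup)
    new("CoreIndex", params = params, entries = entries,
        provenance = provenance, lookup = lookup,
        coreLengths = sort(unique(nchar(names(entries)))),
        groupIds = groupIds(groups), nExcluded = sum(!keep))
}

#' Match one read against a core index
#'
#' A read matches a functional group when some substring of the read is
#' exactly equal to a core carried by that group. Because the core omits
#' the miRNA ends, reads shifted or extended at either end (5'/3' isomiRs,
#' within the trim widths) still contain the core and match, while any
#' internal substitution inside the core (a polymorphic isomiR) destroys
#' the exact match. Reads shorter than `minReadLen` or longer than
#' `maxReadLen` never match.
#'
#' @param readSequence a single normalized read sequence.
#' @param index a [CoreIndex-class].
#' @return sorted character vector of matched group ids (possibly empty).
#' @seealso [naiveMatch()] for the index-free reference implementation.
#' @export
matchRead <- function(readSequence, index) {
    stopifnot(is(index, "CoreIndex"), length(readSequence) == 1L)
    n <- nchar(readSequence)
    p <- index@params
    if (n < p@minReadLen || n > p@maxReadLen)
        return(character(0))
    lookup <- index@lookup
    hits <- character(0)
    for (L in index@coreLengths) {
        if (L > n)
            break
        starts <- seq_len(n - L + 1L)
        subs <- unique(substring(readSequence, starts, starts + L - 1L))
        for (s in subs) {
            g <- get0(s, envir = lookup, inherits = FALSE)
            if (!is.null(g))
                hits <- c(hits, g)
        }
    }
    lexSort(unique(hits))
}

#' Index-free reference matcher
#'
#' Same contract as [matchRead()], implemented by scanning every
#' (read, miRNA) pair and testing core containment with a direct substring
#' search, with no index structure. Intended as an independent check of the
#' indexed matcher; quadratic, so only suitable for small references.
#'
#' @param readSequence a single normalized read sequence.
#' @param mirnas a [MiRNAReference-class].
#' @param groups a [GroupTable-class] covering `mirnas`.
#' @param params a [CoreParams-class].
#' @return sorted character vector of matched group ids (possibly empty).
#' @export
naiveMatch <- function(readSequence, mirnas, groups, params = coreParams()) {
    stopifnot(is(mirnas, "MiRNAReference"), is(groups, "GroupTable"),
              length(readSequence) == 1L)
    n <- nchar(readSequence)
    if (n < params@minReadLen || n > params@maxReadLen)
        return(character(0))
    assign <- groups@assignments
    hits <- character(0)
    for (i in seq_along(mirnas)) {
        core <- extractCore(as.character(mirnas[[i]]), params)
        if (is.na(core) || grepl("N", core, fixed = TRUE))
            next
        if (grepl(core, readSequence, fixed = TRUE))
            hits <- c(hits, unname(assign[[mirnaIds(mirnas)[i]]]))
    }
    lexSort(unique(hits))
}
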