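#' Build a functional-group table under a collapsing scheme
#'
#' Three schemes are supported. `"none"` performs no collapsing: every miRNA
#' is its own singleton group. `"mimat"` collapses miRNAs sharing the same
#' accession before the first underscore, so individualized or
#' duplicated-locus entries such as `MIMAT0000001_1` / `MIMAT0000001_2` fall
#' into group `MIMAT0000001`; miRNAs without an accession stay singletons
#' keyed by their name. `"name"` collapses miRNAs sharing family class, core
#' number, letter (when present) and 5p/3p arm, dropping any locus index, so
#' `mmu-mir-9-2-5p` and `mmu-mir-9-3-5p` share group `miR-9-5p` while
#' `mmu-miR-9a-5p` would not. The species prefix is dropped from name-based
#' group ids (input is assumed to be a single-species reference). Names
#' that do not parse fall back to singleton groups with a warning.
#'
#' @param mirnas a [MiRNAReference-class].
#' @param scheme one of `"none"`, `"mimat"`, `"name"`.
#' @return A [GroupTable-class] covering every miRNA exactly once.
#' @examples
#' ref <- MiRNAReference(
#'     c("UGGAAUGUAAAGAAGUAUGUAU", "UGGAAUGUAAAGAAGUAUGUAU",
#'       "ACUGCAUUAUGAGCACUUAAAG"),
#'     ids = c("mmu-mir-9-2-5p", "mmu-mir-9-3-5p", "mmu-miR-9a-5p"),
#'     accessions = c("MIMAT0000009_1", "MIMAT0000009_2", "MIMAT0000099"))
#' groupAssignments(buildGroups(ref, "name"))
#' @export
buildGroups <- function(mirnas, scheme = c("none", "mimat", "name")) {
    stopifnot(is(mirnas, "MiRNAReference"))
    scheme <- match.arg(scheme)
    if (length(mirnas) == 0L)
        stop("empty reference: cannot build groups", call. = FALSE)
    ids <- mirnaIds(mirnas)
    grp <- switch(scheme,
        none = ids,
        mimat = {
            acc <- sub("_.*$", "", accessions(mirnas))
            ifelse(nzchar(acc), acc, ids)
        },
        name = {
            key <- parseMiRNAName(ids)
            bad <- !key$parse_ok
            if (any(bad))
                warning("name grouping: ", sum(bad), " miRNA name(s) did not ",
                        "parse and were kept as singleton groups: ",
                        paste(utils::head(ids[bad], 5L), collapse = ", "),
                        call. = FALSE)
            canon <- paste0(key$family_class, "-", key$core_number, key$letter,
                            ifelse(nzchar(key$arm), paste0("-", key$arm), ""))
            ifelse(bad, ids, canon)
        })
    GroupTable(scheme, stats::setNames(unname(grp), ids))
}

#' Test whether one group table coarsens another
#'
#' `coarse` is a coarsening of `fine` when every pair of miRNAs sharing a
#' group in `fine` also shares a group in `coarse` (each fine group is
#' contained in a single coarse group). The singleton grouping is the finest
#' partition, so it is refined by every table over the same miRNA set, and
#' every table coarsens itself.
#'
#' @param fine,coarse [GroupTable-class] objects over the same miRNA set.
#' @return logical scalar.
#' @export
isCoarsening <- function(fine, coarse) {
    stopifnot(is(fine, "GroupTable"), is(coarse, "GroupTable"))
    fa <- fine@assignments
    ca <- coarse@assignments
    if (!setequal(names(fa), names(ca)))
        stop("domain mismatch: the two group tables cover different miRNA sets",
             call. = FALSE)
    ca <- ca[names(fa)]
    all(vapply(split(unname(ca), unname(fa)),
               function(g) length(unique(g)) == 1L, logical(1)))
}
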