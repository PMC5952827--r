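#' Construct simulation parameters
#'
#' Defaults describe a realistic small RNA-seq study: mature lengths in the
#' canonical 19-23 nt band, strongly right-skewed per-family abundances
#' (log-normal on the natural-log scale), 3' isomiRs as the most frequent
#' isomiR class, a modest rate of 5' and polymorphic isomiRs, end shifts of
#' up to 2 nt, and a background of non-miRNA degradation fragments spanning
#' 16-30 nt.
#'
#' @param nFamilies,pDuplicateLocus,mirnaLenRange,abundanceMeanlog,
#'   abundanceSdlog,frac5p,frac3p,fracPolymorphic,maxEndShift,nMirnaReads,
#'   nBackgroundReads,seqErrorRate,seed see [SimParams-class].
#' @return A [SimParams-class] object.
#' @examples
#' simParams(nFamilies = 10, seed = 42)
#' @export
simParams <- function(nFamilies = 50, pDuplicateLocus = 0.3,
                      mirnaLenRange = c(19, 23),
                      abundanceMeanlog = 3, abundanceSdlog = 1.5,
                      frac5p = 0.10, frac3p = 0.25, fracPolymorphic = 0.05,
                      maxEndShift = 2, nMirnaReads = 5000,
                      nBackgroundReads = 2000, seqErrorRate = 0.001,
                      seed = 1) {
    new("SimParams", nFamilies = as.integer(nFamilies),
        pDuplicateLocus = pDuplicateLocus,
        mirnaLenRange = as.integer(mirnaLenRange),
        abundanceMeanlog = abundanceMeanlog, abundanceSdlog = abundanceSdlog,
        frac5p = frac5p, frac3p = frac3p, fracPolymorphic = fracPolymorphic,
        maxEndShift = as.integer(maxEndShift),
        nMirnaReads = as.integer(nMirnaReads),
        nBackgroundReads = as.integer(nBackgroundReads),
        seqErrorRate = seqErrorRate, seed = as.integer(seed))
}

randomSequence <- function(len) {
    paste(sample(BASES, len, replace = TRUE), collapse = "")
}

containsAny <- function(read, patterns) {
    for (p in patterns)
        if (grepl(p, read, fixed = TRUE))
            return(TRUE)
    FALSE
}

#' Simulate a mature miRNA reference with family structure
#'
#' Generates `nFamilies` miRNA families named with the miRBase-like grammar
#' (`sim-miR-<number><letter?>(-<locus>)?(-<arm>)?`), so that grouping by
#' name or by accession prefix reconstructs the simulated families exactly.
#' With probability `pDuplicateLocus` a family has two loci with identical
#' mature sequences, distinguished by a locus index in the name
#' (`sim-miR-7-1-5p`, `sim-miR-7-2-5p`) and an underscore suffix on the
#' shared accession (`MIMAT0000007_1`, `MIMAT0000007_2`). Sequences are
#' rejection-sampled so that no family's core (under `params`) occurs
#' inside any other family's mature sequence, making cores unique across
#' distinct groups.
#'
#' @param sim a [SimParams-class].
#' @param params the [CoreParams-class] that will be used downstream; core
#'   uniqueness is enforced with respect to these trims.
#' @return list with elements `reference` (a [MiRNAReference-class]) and
#'   `groups` (the ground-truth [GroupTable-class], scheme `"truth"`, whose
#'   group ids equal the canonical name-scheme ids).
#' @examples
#' sim <- simulateReference(simParams(nFamilies = 5, seed = 7))
#' sim$reference
#' @export
simulateReference <- function(sim, params = coreParams()) {
    stopifnot(is(sim, "SimParams"), is(params, "CoreParams"))
    validObject(sim)
    set.seed(sim@seed)
    lo <- sim@mirnaLenRange[1L]
    hi <- sim@mirnaLenRange[2L]
    ids <- character(0); acc <- character(0); seqs <- character(0)
    truth <- character(0)
    existingCores <- character(0)
    for (i in seq_len(sim@nFamilies)) {
        letter <- sample(c("", "a", "b"), 1L, prob = c(0.7, 0.2, 0.1))
        arm <- sample(c("5p", "3p", ""), 1L, prob = c(0.45, 0.45, 0.10))
        stem <- paste0("sim-miR-", i, letter)
        groupId <- paste0("miR-", i, letter,
                          if (nzchar(arm)) paste0("-", arm) else "")
        base <- sprintf("MIMAT%07d", i)
        ok <- FALSE
        for (try in seq_len(200L)) {
            s <- randomSequence(sample(lo:hi, 1L))
            core <- extractCore(s, params)
            # no established core inside the candidate, and (if admissible)
            # the candidate's core inside no established sequence
            if (containsAny(s, existingCores))
                next
            if (!is.na(core) && any(vapply(seqs, function(e)
                    grepl(core, e, fixed = TRUE), logical(1))))
                next
            ok <- TRUE
            break
        }
        if (!ok)
            stop("could not generate a core-unique sequence for family ", i,
                 " after 200 attempts; widen mirnaLenRange", call. = FALSE)
        dup <- stats::runif(1L) < sim@pDuplicateLocus
        if (dup) {
            locusIds <- paste0(stem, "-", 1:2,
                               if (nzchar(arm)) paste0("-", arm) else "")
            ids <- c(ids, locusIds)
            acc <- c(acc, paste0(base, "_", 1:2))
            seqs <- c(seqs, s, s)
            truth <- c(truth, stats::setNames(rep(groupId, 2L), locusIds))
        } else {
            id <- paste0(stem, if (nzchar(arm)) paste0("-", arm) else "")
            ids <- c(ids, id)
            acc <- c(acc, base)
            seqs <- c(seqs, s)
            truth <- c(truth, stats::setNames(groupId, id))
        }
        if (!is.na(extractCore(s, params)))
            existingCores <- c(existingCores, extractCore(s, params))
    }
    list(reference = MiRNAReference(seqs, ids = ids, accessions = acc),
         groups = GroupTable("truth", truth))
}

# Length distribution of background (non-miRNA) fragments: a mixture over
# 16-30 nt with most mass outside the 19-23 nt miRNA band, emulating
# degradation fragments and other small RNA species.
backgroundLengthWeights <- function() {
    len <- 16:30
    w <- ifelse(len >= 19 & len <= 23, 1, 3)
    stats::setNames(w / sum(w), len)
}

# Probability that a miRNA-derived read falls in [minLen, maxLen], by exact
# enumeration over the length/class/shift model.
mirnaInRangeProb <- function(sim, minLen = 19, maxLen = 23) {
    lens <- sim@mirnaLenRange[1L]:sim@mirnaLenRange[2L]
    pc <- 1 - sim@frac5p - sim@frac3p - sim@fracPolymorphic
    pIso <- sim@frac5p + sim@frac3p
    shifts <- seq_len(sim@maxEndShift)
    p <- 0
    for (L in lens) {
        pl <- 1 / length(lens)
        inr <- function(x) as.numeric(x >= minLen & x <= maxLen)
        p <- p + pl * (pc + sim@fracPolymorphic) * inr(L)
        # isomiR: deletion or extension with equal probability, shift
        # magnitude uniform on 1..maxEndShift
        for (d in shifts)
            p <- p + pl * pIso * (1 / length(shifts)) *
                 0.5 * (inr(L - d) + inr(L + d))
    }
    p
}

#' Background read count needed to hit a target miRNA-read fraction
#'
#' Computes how many background reads to add so that the expected fraction
#' of library reads in the 19-23 nt band equals `targetFraction`, using the
#' exact in-band probabilities of the miRNA-read model and of the
#' background length mixture.
#'
#' @param sim a [SimParams-class] (its `nMirnaReads` and read-class model
#'   are used).
#' @param targetFraction desired fraction of reads in the 19-23 nt band;
#'   must lie strictly between the background in-band probability and the
#'   miRNA-read in-band probability.
#' @return integer number of background reads.
#' @export
backgroundReadsForFraction <- function(sim, targetFraction) {
    stopifnot(is(sim, "SimParams"))
    pm <- mirnaInRangeProb(sim)
    pb <- sum(backgroundLengthWeights()[as.character(19:23)])
    if (targetFraction <= pb || targetFraction >= pm)
        stop("targetFraction must lie strictly between the background ",
             "in-band probability (", signif(pb, 3),
             ") and the miRNA-read in-band probability (", signif(pm, 3), ")",
             call. = FALSE)
    nm <- sim@nMirnaReads
    as.integer(round(nm * (pm - targetFraction) / (targetFraction - pb)))
}

#' Simulate a small RNA-seq read library with ground truth
#'
#' Draws per-family abundances from the log-normal model, assigns each of
#' `nMirnaReads` reads a source family and an isomiR class (canonical, 5'
#' isomiR, 3' isomiR, polymorphic), applies end shifts (deletion or
#' untemplated extension of up to `maxEndShift` nt, equally likely) or one
#' internal substitution inside the core for polymorphic reads, adds
#' `nBackgroundReads` random fragments, and applies a flat per-base
#' substitution error. Reads whose random modifications would accidentally
#' contain a core of a *different* family are resampled, and background
#' reads are resampled until they contain no reference core at all, so
#' label and match structure agree by construction. A read is *countable*
#' when its source miRNA has an admissible core, its end deletions fit
#' within the declared trims, its length passes the read-length gates, and
#' no sequencing error fell inside the core.
#'
#' @param reference a [MiRNAReference-class] from [simulateReference()].
#' @param truthGroups the ground-truth [GroupTable-class]; members of one
#'   family must share an identical mature sequence.
#' @param sim a [SimParams-class].
#' @param params the declared [CoreParams-class] (defines cores, trims and
#'   read-length gates for the countable labels).
#' @return list with elements `reads` (a named `DNAStringSet`; names embed
#'   read index, source family and class) and `truth` (a
#'   [SimTruth-class]).
#' @export
simulateReads <- function(reference, truthGroups, sim,
                          params = coreParams()) {
    stopifnot(is(reference, "MiRNAReference"), is(truthGroups, "GroupTable"),
              is(sim, "SimParams"))
    set.seed((sim@seed + 1L) %% 2147483647L)
    assign <- truthGroups@assignments
    families <- groupIds(truthGroups)
    familyMembers <- split(names(assign), unname(assign))[families]
    # representative locus per family (duplicated loci are identical)
    repSeq <- vapply(familyMembers, function(m)
        as.character(reference)[[m[1L]]], character(1))
    repCore <- extractCore(repSeq, params)
    allCores <- repCore[!is.na(repCore)]

    nm <- sim@nMirnaReads
    classProbs <- c(canonical = 1 - sim@frac5p - sim@frac3p -
                                sim@fracPolymorphic,
                    iso5p = sim@frac5p, iso3p = sim@frac3p,
                    polymorphic = sim@fracPolymorphic)
    w <- stats::rlnorm(length(families), sim@abundanceMeanlog,
                       sim@abundanceSdlog)
    famIdx <- if (nm > 0L) sample(seq_along(families), nm, replace = TRUE,
                                  prob = w) else integer(0)
    cls <- if (nm > 0L) sample(names(classProbs), nm, replace = TRUE,
                               prob = classProbs) else character(0)

    t5 <- params@trim5; t3 <- params@trim3
    n <- nm + sim@nBackgroundReads
    seqs <- character(n); grp <- character(n); mirna <- character(n)
    klass <- character(n); countable <- logical(n)
    for (r in seq_len(nm)) {
        f <- famIdx[r]
        s <- repSeq[f]; L <- nchar(s)
        coreOk <- !is.na(repCore[f])
        foreign <- allCores[names(allCores) != families[f]]
        coreStart <- t5 + 1L          # core span in read coordinates
        coreEnd <- L - t3
        cnt <- coreOk
        read <- s
        if (cls[r] == "iso5p" || cls[r] == "iso3p") {
            d <- sample.int(sim@maxEndShift, 1L)
            if (stats::runif(1L) < 0.5) {         # templated end deletion
                if (cls[r] == "iso5p") {
                    read <- substring(s, 1L + d)
                    coreStart <- coreStart - d; coreEnd <- coreEnd - d
                    cnt <- coreOk && d <= t5
                } else {
                    read <- substring(s, 1L, L - d)
                    cnt <- coreOk && d <= t3
                }
            } else {                              # untemplated extension
                repeat {
                    ext <- randomSequence(d)
                    cand <- if (cls[r] == "iso5p") paste0(ext, read)
                            else paste0(read, ext)
                    if (!containsAny(cand, foreign))
                        break
                }
                read <- cand
                if (cls[r] == "iso5p") {
                    coreStart <- coreStart + d; coreEnd <- coreEnd + d
                }
                cnt <- coreOk
            }
        } else if (cls[r] == "polymorphic") {
            span <- if (coreOk) coreStart:coreEnd else 2:(L - 1L)
            repeat {
                pos <- if (length(span) == 1L) span else sample(span, 1L)
                old <- substring(read, pos, pos)
                cand <- read
                substring(cand, pos, pos) <- sample(setdiff(BASES, old), 1L)
                if (!containsAny(cand, allCores))
                    break
            }
            read <- cand
            cnt <- FALSE
        }
        # flat sequencing error
        if (sim@seqErrorRate > 0) {
            hit <- which(stats::runif(nchar(read)) < sim@seqErrorRate)
            for (pos in hit) {
                old <- substring(read, pos, pos)
                substring(read, pos, pos) <- sample(setdiff(BASES, old), 1L)
            }
            if (length(hit) && any(hit >= coreStart & hit <= coreEnd))
                cnt <- FALSE
        }
        rl <- nchar(read)
        if (rl < params@minReadLen || rl > params@maxReadLen)
            cnt <- FALSE
        seqs[r] <- read
        grp[r] <- families[f]
        mirna[r] <- familyMembers[[f]][1L]
        klass[r] <- cls[r]
        countable[r] <- cnt
    }
    if (sim@nBackgroundReads > 0L) {
        bgw <- backgroundLengthWeights()
        bgLens <- sample(as.integer(names(bgw)), sim@nBackgroundReads,
                         replace = TRUE, prob = bgw)
        for (b in seq_len(sim@nBackgroundReads)) {
            repeat {
                read <- randomSequence(bgLens[b])
                if (!containsAny(read, allCores))
                    break
            }
            r <- nm + b
            seqs[r] <- read; grp[r] <- "background"
            mirna[r] <- NA_character_; klass[r] <- "background"
            countable[r] <- FALSE
        }
    }
    readIds <- sprintf("read%06d|%s|%s", seq_len(n), grp, klass)
    perRead <- data.frame(read_id = readIds, mirna_id = mirna,
                          group_id = grp, class = klass,
                          countable = countable, stringsAsFactors = FALSE)
    cc <- stats::setNames(integer(length(families)), families)
    tab <- table(grp[countable])
    cc[names(tab)] <- as.integer(tab)
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- readIds
    list(reads = reads,
         truth = new("SimTruth", perRead = perRead, countableCounts = cc,
                     familyMembers = familyMembers))
}

#' Ground-truth counts in count-table form
#'
#' Returns the simulator's countable ground truth in the same tabular shape
#' as [writeCounts()] output, either at the truth-family level (default) or
#' projected onto an arbitrary grouping: a countable read from family `f`
#' contributes one count to every group of `groupTable` containing a member
#' of `f` (members of a family share an identical sequence, so an exact
#' matcher hits all of them).
#'
#' @param truth a [SimTruth-class].
#' @param groupTable optional [GroupTable-class] to project onto.
#' @return data.frame with columns `group_id` and `count`, dense and sorted
#'   by `group_id`.
#' @export
trueGroupCounts <- function(truth, groupTable = NULL) {
    stopifnot(is(truth, "SimTruth"))
    if (is.null(groupTable)) {
        cc <- truth@countableCounts
        out <- data.frame(group_id = names(cc), count = as.integer(cc),
                          stringsAsFactors = FALSE)
        return(out[order(out$group_id, method = "radix"), , drop = FALSE])
    }
    stopifnot(is(groupTable, "GroupTable"))
    assign <- groupTable@assignments
    counts <- stats::setNames(integer(length(groupIds(groupTable))),
                              groupIds(groupTable))
    for (f in names(truth@countableCounts)) {
        k <- truth@countableCounts[[f]]
        if (k == 0L)
            next
        targets <- unique(unname(assign[truth@familyMembers[[f]]]))
        counts[targets] <- counts[targets] + k
    }
    data.frame(group_id = names(counts), count = as.integer(counts),
               stringsAsFactors = FALSE)
}

#' Write simulated reads as FASTQ
#'
#' Qualities are constant placeholders; quality realism is outside the
#' simulator's scope.
#'
#' @param reads named `DNAStringSet` from [simulateReads()].
#' @param path output path (`.gz` suffix enables compression).
#' @return `path`, invisibly.
#' @export
writeLibraryFastq <- function(reads, path) {
    Biostrings::writeXStringSet(reads, path, format = "fastq",
                                compress = grepl("\\.gz$", path))
    invisible(path)
}

#' Write per-read ground-truth labels as TSV
#'
#' @param truth a [SimTruth-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSimTruth <- function(truth, path) {
    stopifnot(is(truth, "SimTruth"))
    utils::write.table(truth@perRead, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
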