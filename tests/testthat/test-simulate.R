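test_that("the simulator is byte-deterministic given a seed", {
    sp <- simParams(nFamilies = 10, pDuplicateLocus = 0.5, seed = 99)
    a <- simulateReference(sp)
    b <- simulateReference(sp)
    expect_identical(as.character(a$reference), as.character(b$reference))
    expect_identical(groupAssignments(a$groups), groupAssignments(b$groups))

    spr <- simParams(nFamilies = 10, pDuplicateLocus = 0.5,
                     nMirnaReads = 300, nBackgroundReads = 100, seed = 99)
    ra <- simulateReads(a$reference, a$groups, spr)
    rb <- simulateReads(b$reference, b$groups, spr)
    expect_identical(as.character(ra$reads), as.character(rb$reads))
    expect_identical(ra$truth@perRead, rb$truth@perRead)

    fa1 <- tempfile(); fa2 <- tempfile()
    writeReferenceFasta(a$reference, fa1)
    writeReferenceFasta(b$reference, fa2)
    expect_identical(readLines(fa1), readLines(fa2))
    fq1 <- tempfile(); fq2 <- tempfile()
    writeLibraryFastq(ra$reads, fq1)
    writeLibraryFastq(rb$reads, fq2)
    expect_identical(readLines(fq1), readLines(fq2))
})

test_that("duplication probability 1 gives multi-member families that the
           accession and name schemes both recover", {
    sp <- simParams(nFamilies = 12, pDuplicateLocus = 1, seed = 7)
    sim <- simulateReference(sp)
    truthPartition <- split(names(groupAssignments(sim$groups)),
                            unname(groupAssignments(sim$groups)))
    expect_true(all(lengths(truthPartition) >= 2))
    for (scheme in c("mimat", "name")) {
        gt <- buildGroups(sim$reference, scheme)
        expect_identical(length(groupIds(gt)), 12L)
        part <- split(names(groupAssignments(gt)),
                      unname(groupAssignments(gt)))
        expect_setequal(lapply(unname(part), sort),
                        lapply(unname(truthPartition), sort))
    }
})

test_that("without duplication all three schemes give identical partitions", {
    sp <- simParams(nFamilies = 10, pDuplicateLocus = 0, seed = 15)
    sim <- simulateReference(sp)
    parts <- lapply(c("none", "mimat", "name"), function(s) {
        gt <- buildGroups(sim$reference, s)
        unname(lapply(split(names(groupAssignments(gt)),
                            unname(groupAssignments(gt))), sort))
    })
    expect_setequal(parts[[1]], parts[[2]])
    expect_setequal(parts[[1]], parts[[3]])
})

test_that("reference cores are unique across distinct families", {
    sp <- simParams(nFamilies = 30, pDuplicateLocus = 0.5, seed = 23)
    sim <- simulateReference(sp)
    cores <- extractCore(as.character(sim$reference))
    fam <- groupAssignments(sim$groups)[mirnaIds(sim$reference)]
    keep <- !is.na(cores)
    expect_identical(anyDuplicated(unique(data.frame(core = cores[keep],
                                                     fam = fam[keep]))$core),
                     0L)
    # and no core occurs inside another family's mature sequence
    for (i in which(keep)) {
        others <- as.character(sim$reference)[fam != fam[i]]
        expect_false(any(vapply(others, function(s)
            grepl(cores[i], s, fixed = TRUE), logical(1))))
    }
})

test_that("empirical read-class fractions converge to the parameters", {
    sp <- simParams(nFamilies = 20, pDuplicateLocus = 0.3,
                    frac5p = 0.15, frac3p = 0.30, fracPolymorphic = 0.10,
                    nMirnaReads = 10000, nBackgroundReads = 0,
                    seqErrorRate = 0, seed = 41)
    sim <- simulateReference(sp)
    lib <- simulateReads(sim$reference, sim$groups, sp)
    cls <- table(lib$truth@perRead$class) / 10000
    # binomial 4-sigma tolerances at n = 10000
    tol <- function(p) 4 * sqrt(p * (1 - p) / 10000)
    expect_lt(abs(cls[["iso5p"]] - 0.15), tol(0.15))
    expect_lt(abs(cls[["iso3p"]] - 0.30), tol(0.30))
    expect_lt(abs(cls[["polymorphic"]] - 0.10), tol(0.10))
    expect_lt(abs(cls[["canonical"]] - 0.45), tol(0.45))
})

test_that("background reads never contain a reference core", {
    sp <- simParams(nFamilies = 15, nMirnaReads = 50, nBackgroundReads = 500,
                    seed = 57)
    sim <- simulateReference(sp)
    lib <- simulateReads(sim$reference, sim$groups, sp)
    idx <- suppressWarnings(
        buildCoreIndex(sim$reference, buildGroups(sim$reference, "name")))
    bg <- as.character(lib$reads)[lib$truth@perRead$class == "background"]
    hits <- vapply(bg, function(r) length(matchRead(r, idx)), integer(1))
    expect_identical(sum(hits), 0L)
})

test_that("the background-read helper hits a requested in-band fraction", {
    sp <- simParams(nFamilies = 25, nMirnaReads = 4000, seqErrorRate = 0,
                    seed = 63)
    target <- 0.6   # inside the band observed in real libraries (0.50-0.72)
    nb <- backgroundReadsForFraction(sp, target)
    sp2 <- simParams(nFamilies = 25, nMirnaReads = 4000,
                     nBackgroundReads = nb, seqErrorRate = 0, seed = 63)
    sim <- simulateReference(sp2)
    lib <- simulateReads(sim$reference, sim$groups, sp2)
    frac <- countReadsInLengthRange(lib$reads) / length(lib$reads)
    expect_gt(frac, 0.50)
    expect_lt(frac, 0.72)
    expect_lt(abs(frac - target), 0.05)
    expect_error(backgroundReadsForFraction(sp, 0.99), "strictly between")
})

test_that("truth counts project correctly onto coarser and finer groupings", {
    sp <- simParams(nFamilies = 8, pDuplicateLocus = 1, nMirnaReads = 500,
                    nBackgroundReads = 50, seqErrorRate = 0, seed = 71)
    sim <- simulateReference(sp)
    lib <- simulateReads(sim$reference, sim$groups, sp)
    atTruth <- trueGroupCounts(lib$truth)
    expect_identical(sum(atTruth$count), sum(lib$truth@countableCounts))
    # name scheme reproduces the truth families one-to-one
    name <- buildGroups(sim$reference, "name")
    atName <- trueGroupCounts(lib$truth, name)
    expect_identical(sort(atName$count), sort(atTruth$count))
    # singleton scheme doubles every countable read (all families have 2 loci)
    none <- buildGroups(sim$reference, "none")
    atNone <- trueGroupCounts(lib$truth, none)
    expect_identical(sum(atNone$count), 2L * sum(atTruth$count))
})

test_that("pure scenario handles: all-canonical reads, one family", {
    sp <- simParams(nFamilies = 1, pDuplicateLocus = 0, mirnaLenRange = c(20, 23),
                    frac5p = 0, frac3p = 0, fracPolymorphic = 0,
                    nMirnaReads = 1000, nBackgroundReads = 0,
                    seqErrorRate = 0, seed = 83)
    sim <- simulateReference(sp)
    lib <- simulateReads(sim$reference, sim$groups, sp)
    cc <- lib$truth@countableCounts
    expect_identical(length(cc), 1L)
    expect_identical(unname(cc), 1000L)
})

test_that("per-read truth labels are written as a readable TSV", {
    sp <- simParams(nFamilies = 5, nMirnaReads = 100, nBackgroundReads = 20,
                    seed = 91)
    sim <- simulateReference(sp)
    lib <- simulateReads(sim$reference, sim$groups, sp)
    f <- tempfile()
    writeSimTruth(lib$truth, f)
    back <- read.delim(f, stringsAsFactors = FALSE)
    expect_identical(nrow(back), 120L)
    expect_identical(back$class, lib$truth@perRead$class)
})
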