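test_that("core extraction trims ends and enforces the minimum length", {
    p <- coreParams(trim5 = 2, trim3 = 2, minCoreLen = 16)
    expect_identical(extractCore("ACGTACGTACGTACGTACGTAC", p),
                     "GTACGTACGTACGTACGT")
    expect_identical(nchar(extractCore("ACGTACGTACGTACGTACGTAC", p)), 18L)
    p0 <- coreParams(trim5 = 0, trim3 = 0)
    s <- "ACGTACGTACGTACGTACGT"
    expect_identical(extractCore(s, p0), s)
    expect_true(is.na(extractCore("ACGTACGTACGTACGTAC", p)))  # 18 - 4 < 16
    # vectorized
    expect_identical(is.na(extractCore(c(s, "ACGT"), p0)), c(FALSE, TRUE))
})

test_that("index entries use set semantics over groups", {
    s <- "TGGAATGTAAAGAAGTATGTAT"
    refSame <- MiRNAReference(c(s, s), ids = c("m1", "m2"))
    oneGroup <- GroupTable("custom", c(m1 = "g", m2 = "g"))
    idx1 <- buildCoreIndex(refSame, oneGroup)
    expect_identical(length(coreSequences(idx1)), 1L)
    expect_identical(idx1@entries[[1]], "g")
    expect_identical(ambiguousCoreCount(idx1), 0L)

    twoGroups <- GroupTable("none", c(m1 = "m1", m2 = "m2"))
    idx2 <- buildCoreIndex(refSame, twoGroups)
    expect_identical(idx2@entries[[1]], c("m1", "m2"))
    expect_identical(ambiguousCoreCount(idx2), 1L)
})

test_that("short cores are excluded with a warning; empty index errors", {
    ref <- MiRNAReference(c("ACGTACGTACGTACGTACG", "ACCGTTACCGTTACCGTTACCT"),
                          ids = c("short", "long"))
    gt <- buildGroups(ref, "none")
    expect_warning(idx <- buildCoreIndex(ref, gt), "excluded")
    expect_identical(idx@nExcluded, 1L)
    expect_identical(length(idx@groupIds), 2L)  # dense universe kept
    refShort <- MiRNAReference("ACGTACGTACGTACGTACG", ids = "only")
    expect_error(
        suppressWarnings(buildCoreIndex(refShort,
                                        buildGroups(refShort, "none"))),
        "empty index")
})

test_that("matching tolerates end shifts and rejects internal substitutions", {
    core <- "GTACGTACGTACGTACGT"
    ref <- MiRNAReference(paste0("AC", core, "AC"), ids = "m-5p")
    idx <- buildCoreIndex(ref, GroupTable("custom", c(`m-5p` = "g1")))
    # 2 nt 5' shift plus 3' extension: core still contained
    expect_identical(matchRead(paste0("TT", core, "AA"), idx), "g1")
    # full canonical sequence
    expect_identical(matchRead(paste0("AC", core, "AC"), idx), "g1")
    # one internal substitution inside the core destroys the match
    mut <- core
    substring(mut, 9, 9) <- if (substring(mut, 9, 9) == "A") "C" else "A"
    expect_identical(matchRead(paste0("TT", mut, "AA"), idx), character(0))
    # read-length gates
    expect_identical(matchRead(substr(core, 1, 15), idx), character(0))
    expect_identical(matchRead(paste0(core, strrep("A", 20)), idx),
                     character(0))
})

test_that("cores containing N never match, but stay reported", {
    ref <- MiRNAReference(c("ACGTNCGTACGTACGTACGTAC", "TTGGCCAATTGGCCAATTGGCA"),
                          ids = c("withN", "clean"))
    idx <- buildCoreIndex(ref, buildGroups(ref, "none"))
    expect_identical(length(coreSequences(idx)), 2L)
    expect_identical(matchRead("ACGTNCGTACGTACGTACGTAC", idx), character(0))
    expect_identical(matchRead("TTGGCCAATTGGCCAATTGGCA", idx), "clean")
})

test_that("indexed matching equals the index-free scan on random instances", {
    set.seed(101)
    trials <- 0L
    for (trimSetting in c(0L, 1L, 2L, 3L)) {
        p <- coreParams(trim5 = trimSetting, trim3 = trimSetting,
                        minCoreLen = 14)
        for (rep in 1:3) {
            ref <- randomReference(n = 6, lenRange = c(19, 25), params = p)
            gt <- buildGroups(ref, "name")
            idx <- buildCoreIndex(ref, gt, p)
            for (i in 1:60) {
                read <- if (i %% 2 == 0) {
                    # isomiR-like read from a random reference entry
                    s <- as.character(ref)[[sample(length(ref), 1)]]
                    d5 <- sample(0:3, 1); d3 <- sample(0:3, 1)
                    paste0(randomDNA(sample(0:2, 1)),
                           substr(s, 1 + d5, nchar(s) - d3),
                           randomDNA(sample(0:2, 1)))
                } else randomDNA(sample(14:32, 1))
                expect_identical(matchRead(read, idx),
                                 naiveMatch(read, ref, gt, p))
                trials <- trials + 1L
            }
        }
    }
    expect_gte(trials, 700L)
})

test_that("shorter cores (more trimming) never shrink the match set", {
    set.seed(77)
    p1 <- coreParams(trim5 = 1, trim3 = 1, minCoreLen = 12)
    p3 <- coreParams(trim5 = 3, trim3 = 3, minCoreLen = 12)
    ref <- randomReference(n = 8, lenRange = c(20, 24), params = p3)
    gt <- buildGroups(ref, "none")
    i1 <- buildCoreIndex(ref, gt, p1)
    i3 <- buildCoreIndex(ref, gt, p3)
    for (k in 1:100) {
        s <- as.character(ref)[[sample(length(ref), 1)]]
        read <- paste0(randomDNA(sample(0:2, 1)),
                       substr(s, 1 + sample(0:2, 1),
                              nchar(s) - sample(0:2, 1)),
                       randomDNA(sample(0:2, 1)))
        expect_true(all(matchRead(read, i1) %in% matchRead(read, i3)))
    }
})

test_that("a tighter max read length never grows the match set", {
    set.seed(78)
    ref <- randomReference(n = 5)
    gt <- buildGroups(ref, "none")
    wide <- buildCoreIndex(ref, gt, coreParams(maxReadLen = 30))
    tight <- buildCoreIndex(ref, gt, coreParams(maxReadLen = 24))
    for (k in 1:50) {
        s <- as.character(ref)[[sample(length(ref), 1)]]
        read <- paste0(randomDNA(sample(0:4, 1)), s, randomDNA(sample(0:4, 1)))
        expect_true(all(matchRead(read, tight) %in% matchRead(read, wide)))
    }
})

test_that("coarsening the groups never enlarges the per-read match count", {
    sim <- simulateReference(simParams(nFamilies = 12, pDuplicateLocus = 1,
                                       seed = 21))
    ref <- sim$reference
    none <- buildGroups(ref, "none")
    name <- buildGroups(ref, "name")
    iNone <- suppressWarnings(buildCoreIndex(ref, none))
    iName <- suppressWarnings(buildCoreIndex(ref, name))
    set.seed(22)
    for (k in 1:80) {
        s <- as.character(ref)[[sample(length(ref), 1)]]
        read <- paste0(randomDNA(sample(0:2, 1)),
                       substr(s, 1 + sample(0:2, 1), nchar(s)),
                       randomDNA(sample(0:2, 1)))
        expect_lte(length(matchRead(read, iName)),
                   length(matchRead(read, iNone)))
    }
})

test_that("every within-trim end variant of a miRNA still matches its group", {
    p <- coreParams(trim5 = 2, trim3 = 2, minCoreLen = 16)
    s <- "ACGTTGCAACGGTCAAGGTCCAT"  # 23 nt
    ref <- MiRNAReference(s, ids = "m-5p")
    idx <- buildCoreIndex(ref, GroupTable("custom", c(`m-5p` = "g")), p)
    set.seed(5)
    for (d5 in 0:2) for (d3 in 0:2) {
        del <- substr(s, 1 + d5, nchar(s) - d3)
        expect_identical(matchRead(del, idx), "g")
        ext <- paste0(randomDNA(2), s, randomDNA(2))
        if (nchar(ext) <= 30)
            expect_identical(matchRead(ext, idx), "g")
    }
})
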