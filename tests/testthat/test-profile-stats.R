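# Congener-profile statistics and the packaged reference dataset.

test_that("normalization scales to percent and applies the reporting floor", {
    p <- normalizeProfile(c("C10-C10" = 1, "C10-C12" = 1))
    expect_equal(unname(fractions(p)), c(50, 50))
    # all above the default floor: everything retained
    p3 <- normalizeProfile(c("C10-C10" = 997, "C10-C12" = 2, "C12-C12" = 1))
    expect_identical(length(p3), 3L)
    # sub-floor entries are dropped with a message
    expect_message(
        p4 <- normalizeProfile(c("C10-C10" = 1e5, "C10-C12" = 1)),
        "reporting floor")
    expect_identical(length(p4), 1L)
    expect_error(normalizeProfile(c("C10-C10" = 0)), "no positive abundance")
})

test_that("re-normalized fixture columns sum to 100", {
    for (pl in c("pPA2", "pHAL")) {
        p <- suppressMessages(normalizeProfile(referenceProfiles(pl)[[1]]))
        expect_equal(sum(fractions(p)), 100, tolerance = 0.5)
    }
})

test_that("average chain length reproduces the published column summaries", {
    p <- referenceProfiles()
    # the five columns whose printed ACL is consistent with their fractions
    printed <- c(pPA2 = 10.5, pFLU = 11.6, pDAD = 11.8, pHAL = 13.8, pAMB = 13.7)
    for (pl in names(printed))
        expect_equal(round(averageChainLength(p[[pl]]), 1), printed[[pl]], info = pl)
    expect_identical(length(fractions(p$pPA2)), 10L)
    expect_equal(averageChainLength(congenerProfile(c("C10-C10" = 100))), 10)
})

test_that("average chain length is bounded by the extreme per-molecule means", {
    set.seed(42)
    pool <- allDefaultCongeners()
    for (i in 1:20) {
        nm <- sample(pool, 8)
        fr <- structure(runif(8, 0.1, 50), names = nm)
        p <- congenerProfile(fr)
        halves <- vapply(nm, function(s) totalCarbons(parseCongener(s)) / 2, numeric(1))
        acl <- averageChainLength(p)
        expect_true(acl >= min(halves) - 1e-9 && acl <= max(halves) + 1e-9)
    }
})

test_that("main congeners reproduce the highlighted entries at the 10% threshold", {
    p <- referenceProfiles()
    expect_setequal(mainCongeners(p$pHAL),
                    c("C12-C14", "C14-C14", "C14-C14:1", "C14:1-C14:1"))
    expect_setequal(mainCongeners(p$pPA2), c("C10-C10", "C10-C12"))
    # the 10.0% entry is included, the 8.9% entry is not
    expect_true("C10-C14" %in% mainCongeners(p$pANA))
    expect_false("C14-C16:1" %in% mainCongeners(p$pBUG))
    expect_length(mainCongeners(p$pPA2, threshold = 60), 0)
})

test_that("novelty categorization applies the three characteristics", {
    expect_identical(categorizeNovelty("C4-C10"), "length_gap_ge4")
    expect_identical(categorizeNovelty("C13-C13"), "odd_chain")
    expect_identical(categorizeNovelty("C10-C10"), "known")
    # odd chain combined with a chain-level new unsaturation
    expect_setequal(categorizeNovelty("C14:1-C15:1"),
                    c("new_unsaturation", "odd_chain"))
    # gap of exactly 4 counts
    expect_true("length_gap_ge4" %in% categorizeNovelty("C8-C14"))
})

test_that("enlarging the reference list never adds novelty categories", {
    small <- c("C10-C10", "C10-C12")
    full <- referenceCongeners()
    for (nm in c("C13-C14:1", "C4-C10", "C8-C14:1", "C12-C14")) {
        catsSmall <- categorizeNovelty(nm, small)
        catsFull <- categorizeNovelty(nm, union(full, small))
        if (!identical(catsFull, "known"))
            expect_true(all(catsFull %in% catsSmall), info = nm)
    }
})

test_that("the packaged dataset holds 53 distinct congeners, 23 of them novel", {
    tab <- congenerFractionData()
    expect_identical(nrow(tab), 53L)
    expect_identical(length(unique(tab$congener)), 53L)
    expect_identical(sum(tab$novel), 23L)
    # every tabulated nominal m/z agrees with the mass rules
    for (i in seq_len(nrow(tab))) {
        cg <- parseCongener(tab$congener[i])
        ch <- chains(cg)
        expect_identical(mzDeprotonatedNominal(haaFormula(ch[[1]], ch[[2]])),
                         as.integer(tab$mz[i]), info = tab$congener[i])
        expect_identical(compositionLabel(cg), tab$composition[i])
    }
})

test_that("odd-chain shares sum the right entries", {
    p <- congenerProfile(c("C13-C14" = 50, "C14-C14" = 50))
    expect_equal(oddChainShare(p), 50)
    expect_equal(oddChainShare(congenerProfile(c("C10-C10" = 100))), 0)
    # new odd-chain share of the pAMB column is near the published figure
    pAMB <- referenceProfiles("pAMB")[[1]]
    expect_lte(abs(oddChainShare(pAMB, novelOnly = TRUE) - 7.7), 0.5)
})

test_that("profile reports are ordered, annotated and deterministic", {
    p <- referenceProfiles("pPA2")[[1]]
    rep1 <- profileReport(p)
    expect_identical(rep1$congener[1], "C10-C10")   # largest share first
    expect_true(rep1$mainCongener[1])
    expect_identical(rep1$novelty[rep1$congener == "C8-C14"], "length_gap_ge4")
    expect_equal(round(attr(rep1, "averageChainLength"), 1), 10.5)
    f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
    writeReport(rep1, f1)
    writeReport(profileReport(p), f2)
    expect_identical(readLines(f1), readLines(f2))
    empty <- new("CongenerProfile", label = "", provenance = "measured",
                 fractions = structure(numeric(0), names = character(0)))
    expect_error(profileReport(empty), "empty profile")
})
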