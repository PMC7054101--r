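# Ester-cleavage fragment prediction, peak matching and spectrum annotation.

test_that("predicted fragments reproduce the published chain fragment masses", {
    expect_equal(predictFragments(parseCongener("C13-C14:1"), digits = 4),
                 c(229.1809, 241.1809))
    # identical chains collapse to one fragment; nominal rounding 159
    f88 <- predictFragments(parseCongener("C8-C8"))
    expect_length(f88, 1L)
    expect_identical(as.integer(round(f88)), 159L)
    f610 <- predictFragments(parseCongener("C6-C10"))
    expect_identical(as.integer(round(f610)), c(131L, 187L))
})

test_that("fragment matching assigns both chains of the worked example", {
    fm <- matchFragments(workedExampleSpectrum(), list(parseCongener("C13-C14:1")))
    expect_identical(fm$evidence, "both_chains")
    expect_equal(round(fm$frag1Error, 1), 0.4)
    expect_equal(round(fm$frag2Error, 1), 0.8)
    expect_true(fm$positionalNote)
})

test_that("missing fragments degrade the evidence level", {
    empty <- msSpectrum(453.3592)
    fm <- matchFragments(empty, list(parseCongener("C13-C14:1"),
                                     parseCongener("C12-C15:1")))
    expect_identical(unique(fm$evidence), "precursor_only")
    # one observed fragment far from the predictions of a wrong split
    onePeak <- msSpectrum(453.3592, data.frame(mz = 229.1810, intensity = 10))
    fm2 <- matchFragments(onePeak, list(parseCongener("C12-C15:1")))
    expect_identical(fm2$evidence, "precursor_only")
    fm3 <- matchFragments(onePeak, list(parseCongener("C13-C14:1")))
    expect_identical(fm3$evidence, "one_chain")
})

test_that("annotation ranks the true congener first with both-chains evidence", {
    ann <- annotateSpectrum(workedExampleSpectrum())
    expect_identical(ann$congener[1], "C13-C14:1")
    expect_identical(ann$evidence[1], "both_chains")
    expect_true(ann$positionalNote[1])     # both chain orders implied
    expect_false(ann$ambiguous[1])
    expect_true(all(ann$ambiguous[-1]))
})

test_that("unit-resolution annotation resolves co-isolated congeners", {
    k <- enumerationConstraints(toleranceDa = 0.5)
    s <- msSpectrum(301, data.frame(mz = c(131, 159, 187), intensity = c(20, 100, 20)))
    ann <- annotateSpectrum(s, k)
    confirmed <- ann$congener[ann$evidence == "both_chains"]
    expect_setequal(confirmed, c("C8-C8", "C6-C10"))
})

test_that("a fragment-free spectrum yields only ambiguous annotations", {
    ann <- annotateSpectrum(msSpectrum(453.3592))
    expect_true(nrow(ann) > 0)
    expect_identical(unique(ann$evidence), "precursor_only")
    expect_true(all(ann$ambiguous))
})

test_that("annotation of an off-space precursor returns an empty diagnostic result", {
    ann <- annotateSpectrum(msSpectrum(100.0))
    expect_identical(nrow(ann), 0L)
    expect_match(attr(ann, "diagnostic"), "no congener composition")
})

test_that("free fatty acid interference is flagged", {
    hit <- flagFattyAcidInterference(281.2486)
    expect_true("C18H34O2" %in% hit$formula)
    expect_identical(nrow(flagFattyAcidInterference(453.3592)), 0L)
    # tighter-than-error tolerance excludes a near-match
    expect_identical(
        nrow(flagFattyAcidInterference(281.25,
                 enumerationConstraints(tolerancePpm = 1e-6))), 0L)
})

test_that("annotation is deterministic for identical spectrum and config", {
    a1 <- annotateSpectrum(workedExampleSpectrum())
    a2 <- annotateSpectrum(workedExampleSpectrum())
    expect_identical(a1, a2)
})

test_that("matched fragments of both-chains annotations are complementary", {
    # zero-noise spectra for a sample of congeners across the space
    shift <- 18.010565 - 1.007276
    for (nm in c("C10-C10", "C8-C12", "C13-C14:1", "C4-C10", "C14:1-C18:1")) {
        cg <- parseCongener(nm)
        ch <- chains(cg)
        s <- msSpectrum(mzDeprotonated(haaFormula(ch[[1]], ch[[2]])),
                        data.frame(mz = predictFragments(cg),
                                   intensity = rep(10, length(predictFragments(cg)))))
        ann <- annotateSpectrum(s)
        row <- ann[ann$congener == nm, ]
        expect_identical(row$evidence, "both_chains", info = nm)
        f2 <- if (is.na(row$frag2Matched)) row$frag1Matched else row$frag2Matched
        expect_equal(row$frag1Matched + f2, precursorMz(s) + shift,
                     tolerance = 1e-3, info = nm)
    }
})
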