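# Formula arithmetic and exact/nominal mass computation.

test_that("hydroxy fatty acid and HAA formulas follow the composition rules", {
    cases <- list(
        list(chain = chainSpec(13), formula = "C13H26O3"),
        list(chain = chainSpec(14, 1), formula = "C14H26O3"),
        list(chain = chainSpec(4), formula = "C4H8O3"))
    for (cs in cases)
        expect_identical(formulaString(hfaFormula(cs$chain)), cs$formula)

    expect_identical(formulaString(haaFormula(chainSpec(10), chainSpec(10))),
                     "C20H38O5")
    expect_identical(formulaString(haaFormula(chainSpec(13), chainSpec(14, 1))),
                     "C27H50O5")
    # ester condensation is symmetric
    expect_identical(formulaString(haaFormula(chainSpec(13), chainSpec(14, 1))),
                     formulaString(haaFormula(chainSpec(14, 1), chainSpec(13))))
})

test_that("chain validity bounds are enforced", {
    expect_error(chainSpec(3), "carbons")
    expect_error(chainSpec(13, 9), "unsaturations")
    expect_error(chainSpec(13, -1), "unsaturations")
    expect_silent(validObject(chainSpec(6, 2)))   # floor((6-2)/2) = 2
    expect_error(chainSpec(6, 3), "unsaturations")
})

test_that("formula arithmetic is element-wise and rejects negative counts", {
    w <- parseFormula("H2O")
    f <- parseFormula("C13H26O3") + parseFormula("C14H26O3") - w
    expect_identical(formulaString(f), "C27H50O5")
    expect_error(parseFormula("CH4") - parseFormula("O"), "negative")
    expect_error(molecularFormula(N = 2), "unsupported element")
    expect_error(parseFormula("C2XZ3"), "cannot parse|unsupported")
})

test_that("monoisotopic masses match independent hand sums", {
    expect_equal(monoisotopicMass(parseFormula("H2O")), 18.010565, tolerance = 1e-6)
    expect_equal(monoisotopicMass(parseFormula("C13H26O3")), 230.188195, tolerance = 1e-6)
    expect_equal(monoisotopicMass(parseFormula("C27H50O5")), 454.365825, tolerance = 1e-6)
})

test_that("nominal masses use integer atomic masses", {
    expect_identical(nominalMass(parseFormula("C20H38O5")), 358L)
    expect_identical(nominalMass(parseFormula("C16H30O5")), 302L)
    expect_identical(nominalMass(parseFormula("C7H15O3Si")), 175L)
    expect_identical(mzDeprotonatedNominal(parseFormula("C20H38O5")), 357L)
})

test_that("deprotonated m/z reproduces the published calculated values at 4 decimals", {
    expect_equal(mzDeprotonated(parseFormula("C27H50O5"), digits = 4), 453.3586)
    expect_equal(mzDeprotonated(parseFormula("C13H26O3"), digits = 4), 229.1809)
    expect_equal(mzDeprotonated(parseFormula("C14H26O3"), digits = 4), 241.1809)
    expect_error(mzDeprotonated(molecularFormula(C = 2, O = 1)), "hydrogen")
})

test_that("display rounding is half-up with one guard digit", {
    # the HAA 27:1 anion sits just below the 4-decimal half boundary
    expect_equal(mzRound(453.3585486, 4), 453.3586)
    expect_equal(mzRound(229.1809186, 4), 229.1809)
    expect_equal(mzRound(1.00005, 4), 1.0001)   # plain half-up case
})

test_that("ppm deviation matches the published accuracy figures", {
    expect_equal(round(as.numeric(ppmDeviation(453.3592, 453.3586)), 1), 1.3)
    expect_equal(round(as.numeric(ppmDeviation(229.1810, 229.1809)), 1), 0.4)
    expect_equal(as.numeric(ppmDeviation(500, 500)), 0)
    expect_identical(attr(ppmDeviation(499.9, 500), "sign"), -1)
    expect_error(ppmDeviation(100, 0), "positive")
})

test_that("mass additivity holds exactly across the enumeration space", {
    w <- monoisotopicMass(parseFormula("H2O"))
    for (nm in allDefaultCongeners()) {
        cg <- parseCongener(nm)
        ch <- chains(cg)
        lhs <- monoisotopicMass(haaFormula(ch[[1]], ch[[2]]))
        rhs <- monoisotopicMass(hfaFormula(ch[[1]])) +
            monoisotopicMass(hfaFormula(ch[[2]])) - w
        expect_equal(lhs, rhs, tolerance = 1e-10)
    }
})

test_that("fragment m/z values are complementary to the precursor", {
    # f1 + f2 = precursor + (water - proton), checked at 1e-4 Da
    cg <- parseCongener("C13-C14:1")
    ch <- chains(cg)
    f1 <- mzDeprotonated(hfaFormula(ch[[1]]))
    f2 <- mzDeprotonated(hfaFormula(ch[[2]]))
    prec <- mzDeprotonated(haaFormula(ch[[1]], ch[[2]]))
    expect_equal(f1 + f2, prec + 18.010565 - 1.007276, tolerance = 1e-4)
    # and at the published 4-decimal precision
    expect_equal(229.1809 + 241.1809, 453.3586 + 17.0033, tolerance = 2e-4)
})

test_that("rounded monoisotopic [M-H]- equals nominal [M-H]- while the H mass excess permits", {
    # the cumulative hydrogen mass excess crosses the 0.5 Da rounding
    # boundary at 70 hydrogens, so agreement holds up to the C36:1
    # composition and first breaks for fully saturated C36
    for (nm in allDefaultCongeners()) {
        cg <- parseCongener(nm)
        ch <- chains(cg)
        f <- haaFormula(ch[[1]], ch[[2]])
        hCount <- 2L * totalCarbons(cg) - 2L * totalUnsaturations(cg) - 2L
        if (hCount <= 68L) {
            expect_identical(as.integer(round(mzDeprotonated(f))),
                             mzDeprotonatedNominal(f), info = nm)
        } else {
            expect_identical(as.integer(round(mzDeprotonated(f))),
                             mzDeprotonatedNominal(f) + 1L, info = nm)
        }
    }
})

test_that("atomic mass table is pinned", {
    m <- atomicMasses()
    expect_equal(m[["C"]], 12.0)
    expect_equal(m[["H"]], 1.00782503)
    expect_equal(m[["O"]], 15.99491462)
    expect_equal(m[["Si"]], 27.97692654)
    expect_equal(protonMass(), 1.007276)
})
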