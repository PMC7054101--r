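# Shared fixtures and independent oracles for the test suite.

# Brute-force chain-split oracle, independent of chainSplits(): enumerate
# ALL ordered chain pairs in the constraint space and deduplicate by
# unordered name. Used to cross-check the combinatorial enumeration.
bruteForceSplits <- function(N, D, minChain = 4L, maxChain = 18L,
                             maxUnsatPerChain = 1L, maxTotalUnsat = 2L) {
    if (D > maxTotalUnsat) return(character())
    found <- character()
    for (n1 in minChain:maxChain) for (n2 in minChain:maxChain) {
        if (n1 + n2 != N) next
        for (d1 in 0:maxUnsatPerChain) for (d2 in 0:maxUnsatPerChain) {
            if (d1 + d2 != D) next
            if (d1 > (n1 - 2) %/% 2 || d2 > (n2 - 2) %/% 2) next
            a <- paste0("C", n1, if (d1) paste0(":", d1))
            b <- paste0("C", n2, if (d2) paste0(":", d2))
            nm <- if (n1 < n2 || (n1 == n2 && d1 <= d2))
                paste0(a, "-", b) else paste0(b, "-", a)
            found <- c(found, nm)
        }
    }
    sort(unique(found))
}

# Every congener in the default constraint space, as canonical names.
allDefaultCongeners <- function() {
    k <- enumerationConstraints()
    out <- character()
    for (N in (2L * k@minChain):(2L * k@maxChain))
        for (D in 0L:k@maxTotalUnsat)
            out <- c(out, names(chainSplits(N, D, k)))
    unique(out)
}

# The high-resolution worked-example spectrum: HAA 27:1 precursor with its
# two chain fragments, at the published measured m/z values.
workedExampleSpectrum <- function() {
    msSpectrum(453.3592,
               data.frame(mz = c(229.1810, 241.1811), intensity = c(100, 80)),
               id = "HAA27:1")
}
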