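# Canonical congener representation, naming, and combinatorial enumeration
# of chain compositions consistent with a precursor mass.

#' Construct a congener from two chains
#'
#' Chains are stored in canonical order (shorter first; at equal length,
#' fewer unsaturations first), so `congenerSpec(a, b)` and
#' `congenerSpec(b, a)` are identical objects.
#'
#' @param a,b [ChainSpec-class] objects.
#' @return A [CongenerSpec-class] object.
#' @examples
#' canonicalName(congenerSpec(chainSpec(12, 1), chainSpec(10)))  # "C10-C12:1"
#' @export
congenerSpec <- function(a, b) {
    stopifnot(is(a, "ChainSpec"), is(b, "ChainSpec"))
    validObject(a); validObject(b)
    swap <- a@carbons > b@carbons ||
        (a@carbons == b@carbons && a@unsaturations > b@unsaturations)
    if (swap) { tmp <- a; a <- b; b <- tmp }
    new("CongenerSpec", chain1 = a, chain2 = b)
}

#' @describeIn congenerSpec the two chains as a list.
#' @param object a [CongenerSpec-class] object.
#' @export
chains <- function(object) {
    stopifnot(is(object, "CongenerSpec"))
    list(object@chain1, object@chain2)
}

#' @describeIn canonicalName `"Cn[:d]-Cm[:e]"`, canonical chain order.
#' @export
setMethod("canonicalName", "CongenerSpec", function(object) {
    paste0(.chainLabel(object@chain1), "-", .chainLabel(object@chain2))
})

#' @describeIn totalCarbons sum of chain lengths.
#' @export
setMethod("totalCarbons", "CongenerSpec", function(object) {
    object@chain1@carbons + object@chain2@carbons
})

#' @describeIn totalUnsaturations sum of chain double bonds.
#' @export
setMethod("totalUnsaturations", "CongenerSpec", function(object) {
    object@chain1@unsaturations + object@chain2@unsaturations
})

#' Total-composition shorthand "N:D" of a congener
#'
#' @param object a [CongenerSpec-class] object.
#' @return Character such as `"27:1"` (total carbons : total double bonds).
#' @export
compositionLabel <- function(object) {
    sprintf("%d:%d", totalCarbons(object), totalUnsaturations(object))
}

setMethod("show", "CongenerSpec", function(object) {
    cat("CongenerSpec:", canonicalName(object),
        sprintf("(HAA %s, %s, [M-H]- %.4f)\n", compositionLabel(object),
                formulaString(.congenerFormula(object)),
                mzDeprotonated(.congenerFormula(object), digits = 4)))
})

.congenerFormula <- function(c) haaFormula(c@chain1, c@chain2)

#' Parse a canonical congener name
#'
#' Inverse of [canonicalName()]: accepts the grammar `Cn[:d]-Cm[:e]` in any
#' chain order and returns the canonicalized congener.
#'
#' @param s character scalar, e.g. `"C13-C14:1"`.
#' @return A [CongenerSpec-class] object.
#' @examples
#' canonicalName(parseCongener("C14:1-C13"))   # "C13-C14:1"
#' @export
parseCongener <- function(s) {
    stopifnot(is.character(s), length(s) == 1L)
    pat <- "^C([0-9]+)(:([0-9]+))?-C([0-9]+)(:([0-9]+))?$"
    m <- regmatches(s, regexec(pat, s))[[1]]
    if (!length(m)) {
        # locate the first offending character for the error message
        ok <- regexpr("^C[0-9]+(:[0-9]+)?(-C[0-9]+(:[0-9]+)?)?", s)
        at <- if (ok > 0) attr(ok, "match.length") + 1L else 1L
        stop(sprintf("malformed congener name '%s' (near position %d); expected Cn[:d]-Cm[:e]", s, at))
    }
    num <- function(i) if (nzchar(m[i])) as.integer(m[i]) else 0L
    congenerSpec(chainSpec(num(2), num(4)), chainSpec(num(5), num(7)))
}

#' Construct enumeration constraints
#'
#' @param minChain,maxChain per-chain carbon bounds (defaults 4, 18).
#' @param maxUnsatPerChain per-chain double-bond cap (default 1).
#' @param maxTotalUnsat total double-bond cap (default 2).
#' @param tolerancePpm ppm tolerance for high-resolution matching
#'   (default 5).
#' @param toleranceDa optional Da tolerance; setting it switches matching
#'   to unit-resolution nominal masses (e.g. 0.5 for quadrupole data).
#' @return An [EnumerationConstraints-class] object.
#' @export
enumerationConstraints <- function(minChain = 4L, maxChain = 18L,
                                   maxUnsatPerChain = 1L, maxTotalUnsat = 2L,
                                   tolerancePpm = 5, toleranceDa = NA_real_) {
    new("EnumerationConstraints",
        minChain = as.integer(minChain), maxChain = as.integer(maxChain),
        maxUnsatPerChain = as.integer(maxUnsatPerChain),
        maxTotalUnsat = as.integer(maxTotalUnsat),
        tolerancePpm = as.numeric(tolerancePpm),
        toleranceDa = as.numeric(toleranceDa))
}

setMethod("show", "EnumerationConstraints", function(object) {
    mode <- if (is.na(object@toleranceDa))
        sprintf("%.3g ppm (high-resolution)", object@tolerancePpm)
    else sprintf("%.3g Da (unit-resolution)", object@toleranceDa)
    cat(sprintf("EnumerationConstraints: chains C%d-C%d, <=%d unsat/chain, <=%d total, tolerance %s\n",
                object@minChain, object@maxChain, object@maxUnsatPerChain,
                object@maxTotalUnsat, mode))
})

#' All chain pairs consistent with a total composition
#'
#' Enumerates every unordered pair of chains (n1,d1),(n2,d2) with
#' n1+n2 = N and d1+d2 = D inside the constraint space. This is the
#' combinatorial step behind resolving a precursor composition into
#' congeners: complementary ester-cleavage fragments then decide which
#' splits are actually present.
#'
#' @param N total carbons (must allow two chains of at least `minChain`).
#' @param D total double bonds.
#' @param constraints an [EnumerationConstraints-class] object.
#' @return A list of [CongenerSpec-class] objects, named by canonical name,
#'   in deterministic (n1, d1) order; empty when infeasible.
#' @examples
#' names(chainSplits(20, 0))
#' @export
chainSplits <- function(N, D, constraints = enumerationConstraints()) {
    N <- as.integer(N); D <- as.integer(D)
    k <- constraints
    validObject(k)
    out <- list()
    if (D < 0L || D > k@maxTotalUnsat || N < 2L * k@minChain)
        return(out)
    maxD <- function(n) min(k@maxUnsatPerChain, (n - 2L) %/% 2L)
    for (n1 in max(k@minChain, N - k@maxChain):(N %/% 2L)) {
        n2 <- N - n1
        if (n2 > k@maxChain) next
        for (d1 in 0L:min(D, maxD(n1))) {
            d2 <- D - d1
            if (d2 > maxD(n2)) next
            if (n1 == n2 && d1 > d2) next    # unordered: keep canonical only
            cg <- congenerSpec(chainSpec(n1, d1), chainSpec(n2, d2))
            out[[canonicalName(cg)]] <- cg
        }
    }
    out
}

# Neutral HAA formula for a total composition N:D (independent of how the
# carbons split between the chains): C_N H_(2N-2D-2) O5.
.compositionFormula <- function(N, D) {
    molecularFormula(C = N, H = 2L * N - 2L * D - 2L, O = 5L)
}

#' Enumerate congeners consistent with a precursor m/z
#'
#' Scans total compositions N:D in the constraint space and returns every
#' chain split whose deprotonated monoisotopic m/z (ppm mode) or nominal
#' [M-H]- mass (Da mode) lies within tolerance of the observed precursor.
#'
#' @param precursorMz observed precursor m/z (positive).
#' @param constraints an [EnumerationConstraints-class] object; its
#'   `toleranceDa` slot selects unit-resolution mode.
#' @return A `data.frame` with one row per congener: `congener` (canonical
#'   name), `composition` ("N:D"), `theoreticalMz`, `error` (absolute ppm
#'   or Da), `errorSigned`; sorted by absolute error, then canonical name.
#'   Attribute `errorUnit` is `"ppm"` or `"Da"`. Empty when nothing
#'   matches.
#' @examples
#' enumerateCongeners(453.3592)
#' @export
enumerateCongeners <- function(precursorMz, constraints = enumerationConstraints()) {
    stopifnot(is.numeric(precursorMz), length(precursorMz) == 1L, precursorMz > 0)
    k <- constraints
    validObject(k)
    daMode <- !is.na(k@toleranceDa)
    rows <- list()
    for (N in (2L * k@minChain):(2L * k@maxChain)) {
        for (D in 0L:k@maxTotalUnsat) {
            if (2L * N - 2L * D - 2L <= 0L) next
            f <- .compositionFormula(N, D)
            theo <- if (daMode) mzDeprotonatedNominal(f) else mzDeprotonated(f)
            err <- precursorMz - theo
            within <- if (daMode) abs(err) <= k@toleranceDa
                      else abs(err) / theo * 1e6 <= k@tolerancePpm
            if (!within) next
            splits <- chainSplits(N, D, k)
            if (!length(splits)) next
            errVal <- if (daMode) err else err / theo * 1e6
            rows[[length(rows) + 1L]] <- data.frame(
                congener = names(splits),
                composition = sprintf("%d:%d", N, D),
                theoreticalMz = theo,
                error = abs(errVal),
                errorSigned = errVal,
                stringsAsFactors = FALSE)
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(congener = character(), composition = character(),
                   theoreticalMz = numeric(), error = numeric(),
                   errorSigned = numeric(), stringsAsFactors = FALSE)
    out <- out[order(out$error, out$congener), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "errorUnit") <- if (daMode) "Da" else "ppm"
    out
}
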