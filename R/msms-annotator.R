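# Spectrum -> congener inference: enumerate precursor candidates, predict
# ester-cleavage fragments, match against the peak list, rank by evidence.

#' Construct an MS/MS spectrum
#'
#' @param precursorMz precursor m/z ([M-H]- of the intact HAA).
#' @param peaks `data.frame` (or 2-column matrix) with columns `mz` and
#'   `intensity`; rows are sorted by m/z on construction.
#' @param id optional identifier.
#' @param rt optional retention time (seconds).
#' @return A [Spectrum-class] object (negative polarity).
#' @examples
#' msSpectrum(453.3592, data.frame(mz = c(229.1810, 241.1811),
#'                                 intensity = c(100, 80)))
#' @export
msSpectrum <- function(precursorMz, peaks = data.frame(mz = numeric(), intensity = numeric()),
                       id = "", rt = NA_real_) {
    peaks <- as.data.frame(peaks)
    if (!all(c("mz", "intensity") %in% names(peaks)) && ncol(peaks) == 2L)
        names(peaks) <- c("mz", "intensity")
    peaks <- peaks[order(peaks$mz), c("mz", "intensity"), drop = FALSE]
    rownames(peaks) <- NULL
    new("Spectrum", precursorMz = as.numeric(precursorMz), polarity = "negative",
        peaks = peaks, id = as.character(id), rt = as.numeric(rt))
}

#' @describeIn msSpectrum precursor m/z accessor.
#' @param object a [Spectrum-class] object.
#' @export
setMethod("precursorMz", "Spectrum", function(object) object@precursorMz)

#' @describeIn msSpectrum peak list accessor.
#' @export
setMethod("peaks", "Spectrum", function(object) object@peaks)

#' @describeIn msSpectrum spectrum identifier accessor.
#' @export
spectrumId <- function(object) object@id

setMethod("show", "Spectrum", function(object) {
    cat(sprintf("Spectrum%s: precursor m/z %.4f (negative mode), %d fragment peak(s)\n",
                if (nzchar(object@id)) paste0(" '", object@id, "'") else "",
                object@precursorMz, nrow(object@peaks)))
})

#' @describeIn predictFragments deprotonated m/z of each chain's free
#'   hydroxy acid.
#' @export
setMethod("predictFragments", "CongenerSpec", function(object, digits = NA) {
    vals <- unique(vapply(chains(object), function(ch)
        mzDeprotonated(hfaFormula(ch), digits = digits), numeric(1)))
    sort(vals)
})

# Theoretical fragment m/z per chain in current tolerance mode.
.chainFragmentMz <- function(chain, daMode) {
    f <- hfaFormula(chain)
    if (daMode) as.numeric(mzDeprotonatedNominal(f)) else mzDeprotonated(f)
}

.evidenceLevels <- c("precursor_only", "one_chain", "both_chains")

#' Match predicted ester-cleavage fragments against a peak list
#'
#' For each candidate congener, each predicted fragment is assigned to the
#' nearest unclaimed peak within tolerance (single assignment; ties go to
#' the lower m/z). Evidence is `both_chains` when every predicted fragment
#' is matched (a single shared fragment for identical chains),
#' `one_chain` when only one of two is, `precursor_only` otherwise.
#'
#' @param spectrum a [Spectrum-class] object.
#' @param candidates list of [CongenerSpec-class] objects (or character
#'   canonical names), typically the splits enumerated from the precursor.
#' @param constraints an [EnumerationConstraints-class] object; its
#'   tolerance mode governs fragment matching too.
#' @return A `data.frame` with one row per candidate: `congener`,
#'   `evidence`, `frag1Theoretical`, `frag1Matched`, `frag1Error`,
#'   `frag2Theoretical`, `frag2Matched`, `frag2Error` (NA where unmatched;
#'   frag2 columns are NA for identical chains), `positionalNote` (TRUE
#'   when the two chain orders are jointly implied). Errors are absolute
#'   ppm (or Da in unit-resolution mode).
#' @export
matchFragments <- function(spectrum, candidates, constraints = enumerationConstraints()) {
    stopifnot(is(spectrum, "Spectrum"))
    validObject(spectrum)
    k <- constraints
    daMode <- !is.na(k@toleranceDa)
    if (is.character(candidates)) candidates <- lapply(candidates, parseCongener)
    pk <- peaks(spectrum)
    rows <- lapply(candidates, function(cg) {
        chs <- chains(cg)
        identicalChains <- chs[[1]]@carbons == chs[[2]]@carbons &&
            chs[[1]]@unsaturations == chs[[2]]@unsaturations
        theo <- vapply(chs, .chainFragmentMz, numeric(1), daMode = daMode)
        if (identicalChains) theo <- theo[1]
        used <- rep(FALSE, nrow(pk))
        matched <- rep(NA_real_, length(theo))
        err <- rep(NA_real_, length(theo))
        for (i in seq_along(theo)) {
            if (!nrow(pk)) break
            tol <- if (daMode) k@toleranceDa else k@tolerancePpm * theo[i] / 1e6
            d <- abs(pk$mz - theo[i])
            d[used | d > tol] <- Inf
            if (all(is.infinite(d))) next
            j <- which(d == min(d))[1]   # ties: lower m/z wins (peaks sorted)
            used[j] <- TRUE
            matched[i] <- pk$mz[j]
            err[i] <- if (daMode) abs(pk$mz[j] - theo[i])
                      else as.numeric(ppmDeviation(pk$mz[j], theo[i]))
        }
        nMatched <- sum(!is.na(matched))
        evidence <- if (nMatched == length(theo) && nMatched > 0L) "both_chains"
                    else if (nMatched > 0L) "one_chain"
                    else "precursor_only"
        data.frame(
            congener = canonicalName(cg),
            evidence = evidence,
            frag1Theoretical = theo[1], frag1Matched = matched[1], frag1Error = err[1],
            frag2Theoretical = if (length(theo) > 1L) theo[2] else NA_real_,
            frag2Matched = if (length(theo) > 1L) matched[2] else NA_real_,
            frag2Error = if (length(theo) > 1L) err[2] else NA_real_,
            positionalNote = !identicalChains,
            stringsAsFactors = FALSE)
    })
    out <- if (length(rows)) do.call(rbind, rows) else data.frame(
        congener = character(), evidence = character(),
        frag1Theoretical = numeric(), frag1Matched = numeric(), frag1Error = numeric(),
        frag2Theoretical = numeric(), frag2Matched = numeric(), frag2Error = numeric(),
        positionalNote = logical(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "errorUnit") <- if (daMode) "Da" else "ppm"
    out
}

#' Annotate an MS/MS spectrum with ranked congener assignments
#'
#' The full inference chain: candidate congeners are enumerated from the
#' precursor m/z ([enumerateCongeners()]), their ester-cleavage fragments
#' matched against the peak list ([matchFragments()]), and annotations
#' ranked by fragment evidence, then by precursor mass accuracy.
#' Candidates below the evidence floor are retained but flagged
#' `ambiguous`. Free fatty acid compositions isobaric with the precursor
#' (possible false positives under unspecific detection) are reported in
#' the `interference` column.
#'
#' @param spectrum a [Spectrum-class] object.
#' @param constraints an [EnumerationConstraints-class] object.
#' @param evidenceFloor minimal evidence level for an unambiguous call
#'   (default `"both_chains"`, the demonstrated use; lower it to accept
#'   one-sided fragment evidence).
#' @return A `data.frame`: columns of [matchFragments()] plus
#'   `composition`, `precursorTheoreticalMz`, `precursorError` (absolute,
#'   in the active unit), `ambiguous` and `interference`; sorted by
#'   evidence (best first), absolute precursor error, canonical name.
#'   Zero rows (with a `diagnostic` attribute) when no composition lies
#'   within tolerance of the precursor.
#' @examples
#' s <- msSpectrum(453.3592, data.frame(mz = c(229.1810, 241.1811),
#'                                      intensity = c(100, 80)))
#' annotateSpectrum(s)[1, c("congener", "evidence")]
#' @export
annotateSpectrum <- function(spectrum, constraints = enumerationConstraints(),
                             evidenceFloor = c("both_chains", "one_chain", "precursor_only")) {
    stopifnot(is(spectrum, "Spectrum"))
    evidenceFloor <- match.arg(evidenceFloor)
    k <- constraints
    cand <- enumerateCongeners(precursorMz(spectrum), k)
    if (!nrow(cand)) {
        out <- data.frame()
        attr(out, "diagnostic") <- sprintf(
            "no congener composition within tolerance of precursor m/z %.4f",
            precursorMz(spectrum))
        return(out)
    }
    fm <- matchFragments(spectrum, cand$congener, k)
    out <- cbind(
        fm[, "congener", drop = FALSE],
        composition = cand$composition,
        precursorTheoreticalMz = cand$theoreticalMz,
        precursorError = cand$error,
        fm[, setdiff(names(fm), "congener"), drop = FALSE])
    floorRank <- match(evidenceFloor, .evidenceLevels)
    out$ambiguous <- match(out$evidence, .evidenceLevels) < floorRank
    interf <- flagFattyAcidInterference(precursorMz(spectrum), k)
    out$interference <- if (nrow(interf))
        paste(interf$formula, collapse = ";") else ""
    if (nrow(interf))
        warning(sprintf("precursor m/z %.4f is isobaric with free fatty acid(s): %s",
                        precursorMz(spectrum), paste(interf$formula, collapse = ", ")))
    ord <- order(-match(out$evidence, .evidenceLevels), out$precursorError, out$congener)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "errorUnit") <- attr(fm, "errorUnit")
    out
}

#' Free fatty acid compositions isobaric with a precursor m/z
#'
#' Plain (non-esterified) fatty acids CnH(2n-2d)O2 can co-elute with HAAs
#' and, under unspecific detection, be mistaken for them. This scans the
#' fatty-acid composition space (chain lengths up to twice the congener
#' chain bound) for deprotonated compositions within tolerance of the
#' precursor.
#'
#' @param precursorMz observed m/z.
#' @param constraints an [EnumerationConstraints-class] object (tolerance
#'   mode as in [enumerateCongeners()]).
#' @return `data.frame` with columns `formula`, `carbons`, `unsaturations`,
#'   `theoreticalMz`, `error`; empty when nothing is isobaric.
#' @examples
#' flagFattyAcidInterference(281.2486)$formula   # oleic-type C18H34O2
#' @export
flagFattyAcidInterference <- function(precursorMz, constraints = enumerationConstraints()) {
    stopifnot(is.numeric(precursorMz), length(precursorMz) == 1L, precursorMz > 0)
    k <- constraints
    daMode <- !is.na(k@toleranceDa)
    rows <- list()
    for (n in k@minChain:(2L * k@maxChain)) {
        for (d in 0L:k@maxTotalUnsat) {
            if (2L * n - 2L * d <= 0L) next
            f <- molecularFormula(C = n, H = 2L * n - 2L * d, O = 2L)
            theo <- if (daMode) as.numeric(mzDeprotonatedNominal(f)) else mzDeprotonated(f)
            err <- if (daMode) abs(precursorMz - theo)
                   else as.numeric(ppmDeviation(precursorMz, theo))
            tol <- if (daMode) k@toleranceDa else k@tolerancePpm
            if (err > tol) next
            rows[[length(rows) + 1L]] <- data.frame(
                formula = formulaString(f), carbons = n, unsaturations = d,
                theoreticalMz = theo, error = err, stringsAsFactors = FALSE)
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else data.frame(
        formula = character(), carbons = integer(), unsaturations = integer(),
        theoreticalMz = numeric(), error = numeric(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}
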