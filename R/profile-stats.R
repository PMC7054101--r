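# Congener-profile bookkeeping and summary statistics: normalization,
# average chain length, main congeners, novelty categories, odd-chain
# shares, and the packaged reference dataset.

#' Construct a congener profile
#'
#' @param fractions named numeric vector: congener name (any chain order,
#'   canonicalized on construction) -> fraction in percent.
#' @param label profile label, e.g. the expression plasmid.
#' @param provenance `"measured"` (default), `"synthetic"` or `"fixture"`.
#' @return A [CongenerProfile-class] object.
#' @examples
#' congenerProfile(c("C10-C10" = 60, "C10-C12" = 40), label = "demo")
#' @export
congenerProfile <- function(fractions, label = "", provenance = "measured") {
    stopifnot(is.numeric(fractions), length(fractions) > 0L)
    nm <- vapply(names(fractions), function(s) canonicalName(parseCongener(s)),
                 character(1))
    if (anyDuplicated(nm))
        stop(sprintf("duplicate congener(s) after canonicalization: %s",
                     paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    names(fractions) <- nm
    new("CongenerProfile", label = as.character(label),
        fractions = fractions, provenance = provenance)
}

#' @describeIn congenerProfile fraction accessor.
#' @param object a [CongenerProfile-class] object.
#' @export
setMethod("fractions", "CongenerProfile", function(object) object@fractions)

#' @describeIn congenerProfile profile label accessor.
#' @export
profileLabel <- function(object) object@label

#' @describeIn congenerProfile number of congeners in the profile.
#' @export
setMethod("length", "CongenerProfile", function(x) length(x@fractions))

setMethod("show", "CongenerProfile", function(object) {
    cat(sprintf("CongenerProfile '%s' (%s): %d congener(s), total %.1f%%\n",
                object@label, object@provenance, length(object@fractions),
                sum(object@fractions)))
    if (length(object@fractions)) {
        top <- sort(object@fractions, decreasing = TRUE)
        top <- utils::head(top, 5L)
        cat(paste(sprintf("  %-12s %5.1f%%", names(top), top), collapse = "\n"), "\n")
    }
})

#' Normalize raw abundances to percent fractions
#'
#' Scales raw (arbitrary-unit) congener abundances to percent of total.
#' Entries below the reporting floor are dropped with a message; published
#' congener tables behave the same way, which is why their columns sum to
#' 100 only within rounding slack.
#'
#' @param raw named numeric vector of non-negative abundances (at least
#'   one positive), or a [CongenerProfile-class] object to re-normalize.
#' @param floor reporting floor in percent (default 0.05); entries below
#'   it are dropped after scaling.
#' @param label,provenance passed to [congenerProfile()] when `raw` is a
#'   vector.
#' @return A [CongenerProfile-class] object whose fractions sum to 100
#'   (up to the dropped sub-floor mass).
#' @export
normalizeProfile <- function(raw, floor = 0.05, label = "", provenance = "measured") {
    if (is(raw, "CongenerProfile")) {
        label <- raw@label; provenance <- raw@provenance
        raw <- raw@fractions
    }
    if (!length(raw) || all(is.na(raw)) || sum(raw, na.rm = TRUE) <= 0)
        stop("cannot normalize: no positive abundance")
    if (any(raw < 0, na.rm = TRUE))
        stop("abundances must be non-negative")
    raw <- raw[!is.na(raw)]
    frac <- raw / sum(raw) * 100
    drop <- frac < floor
    if (any(drop)) {
        message(sprintf("dropping %d congener(s) below the %.2f%% reporting floor: %s",
                        sum(drop), floor, paste(names(frac)[drop], collapse = ", ")))
        frac <- frac[!drop]
    }
    congenerProfile(frac, label = label, provenance = provenance)
}

.profilePairs <- function(p) {
    specs <- lapply(names(p@fractions), parseCongener)
    data.frame(
        congener = names(p@fractions),
        fraction = unname(p@fractions),
        n1 = vapply(specs, function(s) s@chain1@carbons, integer(1)),
        d1 = vapply(specs, function(s) s@chain1@unsaturations, integer(1)),
        n2 = vapply(specs, function(s) s@chain2@carbons, integer(1)),
        d2 = vapply(specs, function(s) s@chain2@unsaturations, integer(1)),
        stringsAsFactors = FALSE)
}

#' @describeIn averageChainLength fraction-weighted mean of (n + m)/2.
#' @export
setMethod("averageChainLength", "CongenerProfile", function(object) {
    if (!length(object@fractions))
        stop("cannot compute average chain length of an empty profile")
    tab <- .profilePairs(object)
    sum(tab$fraction * (tab$n1 + tab$n2) / 2) / sum(tab$fraction)
})

#' Main congeners of a profile
#'
#' Congeners whose fraction reaches the threshold, the convention used to
#' highlight a strain's dominant products (default 10%, inferred from the
#' highlighting pattern of published congener tables: 10.0 is a main
#' congener, 8.9 is not).
#'
#' @param p a [CongenerProfile-class] object.
#' @param threshold minimal fraction in percent (default 10).
#' @return Character vector of canonical congener names, largest fraction
#'   first; empty for an empty profile.
#' @examples
#' mainCongeners(referenceProfiles()[["pPA2"]])
#' @export
mainCongeners <- function(p, threshold = 10.0) {
    stopifnot(is(p, "CongenerProfile"))
    fr <- sort(p@fractions[p@fractions >= threshold], decreasing = TRUE)
    names(fr)
}

#' Novelty categories of a congener against a reference list
#'
#' A congener present in the reference list is `"known"`. Otherwise every
#' applicable category is returned: `"length_gap_ge4"` (the two chains
#' differ by four or more carbons), `"new_unsaturation"` (an unsaturated
#' chain, as an exact (length, double bonds) pair, that occurs in no
#' reference congener), `"odd_chain"` (any odd chain length).
#'
#' @param congener a [CongenerSpec-class] object or canonical name.
#' @param reference character vector of canonical congener names treated
#'   as previously reported (default [referenceCongeners()]).
#' @return Character vector: `"known"`, or one or more categories, or
#'   `"uncategorized"` for a new congener fitting no category.
#' @examples
#' categorizeNovelty("C13-C13")   # "odd_chain"
#' @export
categorizeNovelty <- function(congener, reference = referenceCongeners()) {
    if (is.character(congener)) congener <- parseCongener(congener)
    stopifnot(is(congener, "CongenerSpec"))
    name <- canonicalName(congener)
    reference <- vapply(reference, function(s) canonicalName(parseCongener(s)),
                        character(1))
    if (name %in% reference)
        return("known")
    refChains <- unique(unlist(lapply(reference, function(s) {
        ch <- chains(parseCongener(s))
        vapply(ch, .chainLabel, character(1))
    })))
    cats <- character()
    chs <- chains(congener)
    if (abs(chs[[1]]@carbons - chs[[2]]@carbons) >= 4L)
        cats <- c(cats, "length_gap_ge4")
    unsatNew <- vapply(chs, function(ch)
        ch@unsaturations >= 1L && !.chainLabel(ch) %in% refChains, logical(1))
    if (any(unsatNew))
        cats <- c(cats, "new_unsaturation")
    if (chs[[1]]@carbons %% 2L == 1L || chs[[2]]@carbons %% 2L == 1L)
        cats <- c(cats, "odd_chain")
    if (!length(cats)) "uncategorized" else cats
}

#' Summed fraction of odd-chain congeners
#'
#' The percentage of a profile carried by congeners with at least one
#' odd-length chain, optionally restricted to congeners absent from the
#' reference list (i.e. new odd-chain congeners).
#'
#' @param p a [CongenerProfile-class] object.
#' @param novelOnly if TRUE, only congeners not in `reference` count.
#' @param reference canonical names of previously reported congeners.
#' @return Numeric percentage.
#' @export
oddChainShare <- function(p, novelOnly = FALSE, reference = referenceCongeners()) {
    stopifnot(is(p, "CongenerProfile"))
    if (!length(p@fractions)) return(0)
    tab <- .profilePairs(p)
    keep <- (tab$n1 %% 2L == 1L) | (tab$n2 %% 2L == 1L)
    if (novelOnly)
        keep <- keep & !(tab$congener %in% reference)
    sum(tab$fraction[keep])
}

#' Structured report for a congener profile
#'
#' One row per congener with its fraction, nominal [M-H]- m/z, novelty
#' categories and main-congener flag, sorted by fraction (largest first;
#' ties by name). Average chain length and odd-chain shares are attached
#' as attributes. The result serializes deterministically with
#' [writeReport()].
#'
#' @param p a [CongenerProfile-class] object (non-empty).
#' @param reference canonical names of previously reported congeners.
#' @param threshold main-congener threshold in percent (default 10).
#' @return `data.frame` with columns `congener`, `composition`, `mz`,
#'   `fraction`, `novelty` (comma-separated categories), `mainCongener`;
#'   attributes `averageChainLength`, `oddChainShare`,
#'   `oddChainShareNovel`, `label`.
#' @export
profileReport <- function(p, reference = referenceCongeners(), threshold = 10.0) {
    stopifnot(is(p, "CongenerProfile"))
    acl <- averageChainLength(p)    # errors on empty profile
    specs <- lapply(names(p@fractions), parseCongener)
    out <- data.frame(
        congener = names(p@fractions),
        composition = vapply(specs, compositionLabel, character(1)),
        mz = vapply(specs, function(s) mzDeprotonatedNominal(.congenerFormula(s)),
                    integer(1)),
        fraction = unname(p@fractions),
        novelty = vapply(specs, function(s)
            paste(categorizeNovelty(s, reference), collapse = ","), character(1)),
        mainCongener = unname(p@fractions) >= threshold,
        stringsAsFactors = FALSE)
    out <- out[order(-out$fraction, out$congener), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "averageChainLength") <- acl
    attr(out, "oddChainShare") <- oddChainShare(p, FALSE, reference)
    attr(out, "oddChainShareNovel") <- oddChainShare(p, TRUE, reference)
    attr(out, "label") <- p@label
    out
}

# ---- packaged reference dataset -------------------------------------------

.fixturePath <- function() {
    system.file("extdata", "congener_fractions.tsv", package = "haaMS",
                mustWork = TRUE)
}

#' Curated HAA congener-fraction dataset
#'
#' The packaged congener composition table for seven RhlA expression
#' plasmids (pPA2, pFLU, pDAD, pANA, pHAL, pAMB, pBUG) expressed in an
#' E. coli host: 53 distinct congeners with per-plasmid percent fractions
#' and a flag marking congeners not reported before that dataset.
#'
#' @return `data.frame` with columns `composition` ("N:D"), `mz` (nominal
#'   [M-H]-), `congener` (canonical name), `novel` (logical) and one
#'   numeric fraction column per plasmid (NA where not detected).
#' @examples
#' nrow(congenerFractionData())   # 53
#' @export
congenerFractionData <- function() {
    tab <- utils::read.delim(.fixturePath(), stringsAsFactors = FALSE)
    tab$novel <- as.logical(tab$novel)
    tab
}

#' Reference congener profiles from the packaged dataset
#'
#' @param plasmids which fraction columns to return (default all seven).
#' @return Named list of [CongenerProfile-class] objects with provenance
#'   `"fixture"`; NA fractions (congener not detected for that plasmid)
#'   are dropped.
#' @examples
#' round(averageChainLength(referenceProfiles()[["pPA2"]]), 1)   # 10.5
#' @export
referenceProfiles <- function(plasmids = c("pPA2", "pFLU", "pDAD", "pANA",
                                           "pHAL", "pAMB", "pBUG")) {
    tab <- congenerFractionData()
    missing <- setdiff(plasmids, names(tab))
    if (length(missing))
        stop(sprintf("unknown plasmid column(s): %s (available: %s)",
                     paste(missing, collapse = ", "),
                     paste(setdiff(names(tab), c("composition", "mz", "congener", "novel")),
                           collapse = ", ")))
    out <- lapply(plasmids, function(pl) {
        fr <- structure(tab[[pl]], names = tab$congener)
        fr <- fr[!is.na(fr)]
        congenerProfile(fr, label = pl, provenance = "fixture")
    })
    names(out) <- plasmids
    out
}

#' Previously reported congeners (the reference list for novelty calls)
#'
#' @return Character vector of canonical congener names: the rows of the
#'   packaged dataset not flagged as novel.
#' @export
referenceCongeners <- function() {
    tab <- congenerFractionData()
    sort(tab$congener[!tab$novel])
}
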