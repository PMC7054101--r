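# EI fragment prediction for hydrolyzed, methylated, trimethylsilylated
# hydroxy fatty acids, and chain assignment from GC-MS peak lists.

#' Formula of a methylated, trimethylsilylated hydroxy fatty acid
#'
#' The standard GC derivatization pipeline: hydrolysis releases the free
#' hydroxy acid, methylation gives the methyl ester (+CH2), and
#' trimethylsilylation of the hydroxy group replaces its hydrogen with
#' Si(CH3)3 (+C3H8Si).
#'
#' @param chain a [ChainSpec-class] object.
#' @return A [MolecularFormula-class] object.
#' @examples
#' formulaString(derivatizedFormula(chainSpec(13)))   # "C17H36O3Si"
#' @export
derivatizedFormula <- function(chain) {
    hfaFormula(chain) + molecularFormula(C = 1, H = 2) +
        molecularFormula(C = 3, H = 8, Si = 1)
}

#' Chain-length diagnostic [M-15]+ ion
#'
#' Electron ionization of the FAME-TMS derivative loses a methyl radical;
#' the resulting [M-15]+ ion determines the chain length at unit
#' resolution (homologs are spaced 14 Da apart; each double bond shifts
#' the ion by -2).
#'
#' @param chain a [ChainSpec-class] object.
#' @return Integer m/z.
#' @examples
#' mMinus15(chainSpec(13))   # 301
#' @export
mMinus15 <- function(chain) {
    nominalMass(derivatizedFormula(chain)) - 15L
}

#' Hydroxy-position diagnostic EI fragment
#'
#' Cleavage next to the OTMS carbon yields a TMS-oxycarbenium fragment
#' spanning the carboxymethyl end through the hydroxylated carbon. For a
#' 3-hydroxy acid the fragment is C7H15O3Si (m/z 175); each further
#' position adds one CH2.
#'
#' @param hydroxylPosition integer >= 2.
#' @return Integer m/z of the diagnostic fragment.
#' @examples
#' positionDiagnosticMz(3)   # 175
#' @export
positionDiagnosticMz <- function(hydroxylPosition) {
    p <- as.integer(hydroxylPosition)
    if (length(p) != 1L || is.na(p) || p < 2L)
        stop("hydroxylPosition must be a single integer >= 2")
    f <- molecularFormula(C = p + 4L, H = 2L * p + 9L, O = 3L, Si = 1L)
    nominalMass(f)
}

#' Assign hydroxy fatty acid chains from a GC-EI-MS peak list
#'
#' Candidate chains (within the constraint space, double bonds 0 or up to
#' the per-chain cap) whose [M-15]+ ion matches a peak within the window
#' are reported; the 3-hydroxy position is confirmed when the m/z 175
#' diagnostic is also present. Double-bond position is never assigned
#' (EI of the derivative does not localize it).
#'
#' @param peaks `data.frame` with columns `mz` and `intensity` (or a
#'   numeric vector of m/z values), non-empty.
#' @param window matching window in Da (default 0.3, quadrupole scan
#'   data).
#' @param constraints an [EnumerationConstraints-class] object bounding
#'   the chain space.
#' @return `data.frame` with columns `chain` (e.g. `"C13"`), `carbons`,
#'   `unsaturations`, `mMinus15`, `matchedPeakMz`, `positionConfirmed`.
#'   Zero rows when no [M-15]+ matches; if only the position diagnostic
#'   was seen, attribute `diagnosticOnly` is TRUE.
#' @details Peaks are single-assignment: the peak claimed as the position
#'   diagnostic is not reused as an [M-15]+ candidate. This matters for
#'   the shortest chain, whose [M-15]+ coincides with the 3-hydroxy
#'   diagnostic at m/z 175 (a genuine C4 derivative produces both ions,
#'   i.e. two peaks there).
#' @examples
#' assignChainFromEI(c(301, 175))
#' @export
assignChainFromEI <- function(peaks, window = 0.3,
                              constraints = enumerationConstraints()) {
    if (is.numeric(peaks)) peaks <- data.frame(mz = peaks, intensity = 1)
    stopifnot(nrow(peaks) > 0L, all(c("mz", "intensity") %in% names(peaks)))
    k <- constraints
    diagMz <- positionDiagnosticMz(3L)
    available <- rep(TRUE, nrow(peaks))
    dd <- abs(peaks$mz - diagMz)
    diagSeen <- any(dd <= window)
    if (diagSeen)
        available[which.min(dd)] <- FALSE   # diagnostic peak is consumed
    rows <- list()
    for (n in k@minChain:k@maxChain) {
        for (d in 0L:min(k@maxUnsatPerChain, (n - 2L) %/% 2L)) {
            ch <- chainSpec(n, d)
            target <- mMinus15(ch)
            hit <- which(available & abs(peaks$mz - target) <= window)
            if (!length(hit)) next
            hit <- hit[which.min(abs(peaks$mz[hit] - target))]
            rows[[length(rows) + 1L]] <- data.frame(
                chain = .chainLabel(ch), carbons = n, unsaturations = d,
                mMinus15 = target, matchedPeakMz = peaks$mz[hit],
                positionConfirmed = diagSeen, stringsAsFactors = FALSE)
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else data.frame(
        chain = character(), carbons = integer(), unsaturations = integer(),
        mMinus15 = integer(), matchedPeakMz = numeric(),
        positionConfirmed = logical(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "diagnosticOnly") <- diagSeen && !nrow(out)
    out
}
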