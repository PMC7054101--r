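# Central S4 classes. Constructors live next to the methods of each module
# (mass-core.R, congener-space.R, ...); validity is enforced here.

.SUPPORTED_ELEMENTS <- c("C", "H", "O", "Si")

#' MolecularFormula: an element -> count map with mass arithmetic
#'
#' Holds the neutral elemental composition behind every m/z the package
#' computes. Supported elements are C, H, O and Si (Si enters through
#' trimethylsilyl derivatives in the GC-MS module). Formulas add and
#' subtract element-wise via `+` and `-`; subtraction that would drive any
#' count negative is an error.
#'
#' @slot counts named integer vector; names are element symbols, values are
#'   non-negative counts, at least one positive.
#' @seealso [molecularFormula()], [parseFormula()], [monoisotopicMass()],
#'   [nominalMass()], [mzDeprotonated()], [formulaString()]
#' @export
setClass("MolecularFormula", representation(counts = "integer"))

setValidity("MolecularFormula", function(object) {
    cnt <- object@counts
    if (is.null(names(cnt)) || any(!nzchar(names(cnt))))
        return("counts must be a named integer vector")
    bad <- setdiff(names(cnt), .SUPPORTED_ELEMENTS)
    if (length(bad))
        return(sprintf("unsupported element(s): %s", paste(bad, collapse = ", ")))
    if (anyDuplicated(names(cnt)))
        return("duplicated element symbols")
    if (any(is.na(cnt)) || any(cnt < 0L))
        return("all element counts must be non-negative")
    if (sum(cnt) == 0L)
        return("formula must contain at least one atom")
    TRUE
})

#' ChainSpec: a 3-hydroxy fatty acid chain
#'
#' A chain is described by its length (carbon atoms), its number of
#' double bonds, and the position of the hydroxy group (3 for the
#' beta-hydroxy acids that make up HAAs; overridable for the GC-MS
#' position diagnostic). Written `Cn` or `Cn:d` in the field's notation.
#'
#' @slot carbons integer chain length, at least 4.
#' @slot unsaturations integer double-bond count, between 0 and
#'   `floor((carbons - 2)/2)`.
#' @slot hydroxylPosition integer, default 3, at least 2.
#' @seealso [chainSpec()], [hfaFormula()]
#' @export
setClass("ChainSpec", representation(
    carbons = "integer",
    unsaturations = "integer",
    hydroxylPosition = "integer"
))

setValidity("ChainSpec", function(object) {
    n <- object@carbons; d <- object@unsaturations; p <- object@hydroxylPosition
    if (length(n) != 1L || is.na(n) || n < 4L)
        return("carbons must be a single integer >= 4")
    if (length(d) != 1L || is.na(d) || d < 0L || d > (n - 2L) %/% 2L)
        return(sprintf("unsaturations must lie in [0, %d] for a C%d chain", (n - 2L) %/% 2L, n))
    if (length(p) != 1L || is.na(p) || p < 2L)
        return("hydroxylPosition must be a single integer >= 2")
    TRUE
})

#' CongenerSpec: an unordered pair of 3-hydroxy fatty acid chains
#'
#' One HAA congener, stored in canonical order: shorter chain first and,
#' at equal length, fewer unsaturations first. The two positional isomers
#' (which chain carries the free carboxylic acid) are deliberately a single
#' object: ester-cleavage MS/MS cannot tell them apart, so congeners are
#' reported jointly for both chain positions.
#'
#' @slot chain1,chain2 [ChainSpec-class] objects in canonical order.
#' @seealso [congenerSpec()], [parseCongener()], [canonicalName()]
#' @export
setClass("CongenerSpec", representation(chain1 = "ChainSpec", chain2 = "ChainSpec"))

setValidity("CongenerSpec", function(object) {
    a <- object@chain1; b <- object@chain2
    if (a@carbons > b@carbons ||
        (a@carbons == b@carbons && a@unsaturations > b@unsaturations))
        return("chains are not in canonical order (shorter first, then fewer unsaturations)")
    TRUE
})

#' EnumerationConstraints: the chain space and matching tolerance
#'
#' Bounds of the combinatorial chain space searched when resolving a
#' precursor mass, plus the mass-matching tolerance. Exactly one tolerance
#' mode is active: ppm (high-resolution, the default) or Da
#' (unit-resolution triple-quadrupole / EI data, activated by setting
#' `toleranceDa`).
#'
#' @slot minChain,maxChain integer per-chain carbon bounds (defaults 4 and
#'   18, covering the observed congener range C4-C10 through C14:1-C18:1).
#' @slot maxUnsatPerChain integer, default 1 (single-chain polyunsaturation
#'   has not been observed in HAAs).
#' @slot maxTotalUnsat integer, default 2.
#' @slot tolerancePpm positive ppm tolerance, default 5 (the instrument
#'   accuracy criterion for high-resolution assignments).
#' @slot toleranceDa positive Da tolerance or `NA`; when set it replaces
#'   the ppm tolerance and switches matching to nominal masses.
#' @seealso [enumerationConstraints()], [enumerateCongeners()]
#' @export
setClass("EnumerationConstraints", representation(
    minChain = "integer",
    maxChain = "integer",
    maxUnsatPerChain = "integer",
    maxTotalUnsat = "integer",
    tolerancePpm = "numeric",
    toleranceDa = "numeric"
))

setValidity("EnumerationConstraints", function(object) {
    if (object@minChain < 4L)
        return("minChain must be >= 4")
    if (object@minChain > object@maxChain)
        return("minChain must not exceed maxChain")
    if (object@maxUnsatPerChain < 0L || object@maxTotalUnsat < 0L)
        return("unsaturation bounds must be non-negative")
    if (length(object@tolerancePpm) != 1L || is.na(object@tolerancePpm) ||
        object@tolerancePpm <= 0)
        return("tolerancePpm must be a single positive number")
    if (length(object@toleranceDa) != 1L ||
        (!is.na(object@toleranceDa) && object@toleranceDa <= 0))
        return("toleranceDa must be NA or a single positive number")
    TRUE
})

#' Spectrum: one negative-mode MS/MS peak list
#'
#' A precursor m/z plus its fragment peaks. Only negative polarity
#' (deprotonated molecules) is supported; peaks are kept sorted by m/z.
#'
#' @slot precursorMz positive numeric.
#' @slot polarity `"negative"`.
#' @slot peaks `data.frame` with numeric columns `mz` (> 0, ascending) and
#'   `intensity` (>= 0).
#' @slot id character identifier (may be empty).
#' @slot rt retention time in seconds, or `NA`.
#' @seealso [msSpectrum()], [annotateSpectrum()], [readSpectra()]
#' @export
setClass("Spectrum", representation(
    precursorMz = "numeric",
    polarity = "character",
    peaks = "data.frame",
    id = "character",
    rt = "numeric"
))

setValidity("Spectrum", function(object) {
    if (length(object@precursorMz) != 1L || is.na(object@precursorMz) ||
        object@precursorMz <= 0)
        return("precursorMz must be a single positive number")
    if (!identical(object@polarity, "negative"))
        return("only negative polarity (deprotonated ions) is supported")
    pk <- object@peaks
    if (!all(c("mz", "intensity") %in% names(pk)))
        return("peaks must have columns 'mz' and 'intensity'")
    if (nrow(pk)) {
        if (any(pk$mz <= 0) || any(pk$intensity < 0))
            return("peak mz must be > 0 and intensity >= 0")
        if (is.unsorted(pk$mz))
            return("peaks must be sorted ascending by mz")
    }
    TRUE
})

#' CongenerProfile: relative congener abundances for one strain or plasmid
#'
#' A congener -> fraction (%) table, e.g. one column of an HPLC-MS/MS
#' congener composition experiment. Fractions are non-negative;
#' [normalizeProfile()] rescales to a 100% total (a slack of 0.5 is
#' tolerated elsewhere, matching the rounding of published tables).
#'
#' @slot label character (e.g. the expression plasmid name).
#' @slot fractions named numeric vector, names canonical congener names.
#' @slot provenance one of `"measured"`, `"synthetic"`, `"fixture"`.
#' @seealso [congenerProfile()], [averageChainLength()], [mainCongeners()]
#' @export
setClass("CongenerProfile", representation(
    label = "character",
    fractions = "numeric",
    provenance = "character"
))

setValidity("CongenerProfile", function(object) {
    fr <- object@fractions
    if (length(fr) && (is.null(names(fr)) || any(!nzchar(names(fr)))))
        return("fractions must be named by congener")
    if (anyDuplicated(names(fr)))
        return("duplicated congener names")
    if (any(is.na(fr)) || any(fr < 0))
        return("fractions must be non-negative")
    if (!object@provenance %in% c("measured", "synthetic", "fixture"))
        return("provenance must be 'measured', 'synthetic' or 'fixture'")
    ok <- vapply(names(fr), function(nm)
        !inherits(try(parseCongener(nm), silent = TRUE), "try-error"),
        logical(1))
    if (length(fr) && !all(ok))
        return(sprintf("invalid congener name(s): %s",
                       paste(names(fr)[!ok], collapse = ", ")))
    TRUE
})

.FEATURE_LABELS <- c(
    "rhlA_candidate", "rhlB", "rhlC", "rhlR", "rhlI", "transporter",
    "nodT", "hylD", "methyltransferase", "UDG", "HIB_CoA_hydrolase",
    "unknown_function", "RsuA", "tRNA", "other"
)

#' GeneNeighborhood: ordered gene annotations around a candidate locus
#'
#' The input to the synteny classifier: an ordered list of annotated gene
#' features around exactly one acyltransferase candidate, with a window of
#' genes up/downstream that the rules may consult.
#'
#' @slot features `data.frame` with columns `id` (character), `label`
#'   (controlled vocabulary, see [featureLabels()]), `strand` (`"+"` or
#'   `"-"`) and `ordinal` (unique integers giving gene order along the
#'   locus).
#' @slot window integer, genes up/downstream considered by the rules
#'   (default 5).
#' @seealso [geneNeighborhood()], [classifyLocus()], [readNeighborhood()]
#' @export
setClass("GeneNeighborhood", representation(features = "data.frame", window = "integer"))

setValidity("GeneNeighborhood", function(object) {
    ft <- object@features
    need <- c("id", "label", "strand", "ordinal")
    if (!all(need %in% names(ft)))
        return(sprintf("features must have columns %s", paste(need, collapse = ", ")))
    if (!nrow(ft))
        return("features must not be empty")
    if (anyDuplicated(ft$ordinal))
        return("ordinals must be unique within a neighborhood")
    if (!all(ft$strand %in% c("+", "-")))
        return("strand must be '+' or '-'")
    bad <- setdiff(unique(ft$label), .FEATURE_LABELS)
    if (length(bad))
        return(sprintf("unknown feature label(s): %s", paste(bad, collapse = ", ")))
    ncand <- sum(ft$label == "rhlA_candidate")
    if (ncand != 1L)
        return(sprintf("exactly one rhlA_candidate required, found %d", ncand))
    if (length(object@window) != 1L || is.na(object@window) || object@window < 1L)
        return("window must be a single positive integer")
    TRUE
})
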