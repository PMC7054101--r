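#' @include AllClasses.R
NULL

#' Monoisotopic mass of a molecular formula
#'
#' Sum of the pinned monoisotopic atomic masses (see [atomicMasses()])
#' weighted by element counts.
#'
#' @param object a [MolecularFormula-class] object.
#' @return Mass in Da (numeric scalar, full precision).
#' @seealso [nominalMass()], [mzDeprotonated()]
#' @examples
#' monoisotopicMass(parseFormula("H2O"))
#' @export
setGeneric("monoisotopicMass", function(object) standardGeneric("monoisotopicMass"))

#' Nominal (integer) mass of a molecular formula
#'
#' Integer mass from integer atomic masses (C 12, H 1, O 16, Si 28), the
#' scale used for unit-resolution (triple-quadrupole, EI) spectra.
#'
#' @param object a [MolecularFormula-class] object.
#' @return Integer mass in Da.
#' @export
setGeneric("nominalMass", function(object) standardGeneric("nominalMass"))

#' m/z of the deprotonated molecular anion [M-H]-
#'
#' Neutral monoisotopic mass minus the proton mass (1.007276 Da); the
#' species observed for HAAs in negative-mode electrospray ionization.
#'
#' @param object a [MolecularFormula-class] object (must contain hydrogen).
#' @param digits if a number, the value is rounded half-up with one guard
#'   digit for display (4 reproduces instrument-style reporting); the
#'   default `NA` returns full precision.
#' @return m/z (numeric scalar).
#' @export
setGeneric("mzDeprotonated", function(object, digits = NA) standardGeneric("mzDeprotonated"))

#' Render a formula as text in Hill order
#'
#' @param object a [MolecularFormula-class] object.
#' @return Character scalar such as `"C27H50O5"` (carbon, then hydrogen,
#'   then remaining elements alphabetically; counts of 1 are implicit).
#' @export
setGeneric("formulaString", function(object) standardGeneric("formulaString"))

#' Canonical congener name
#'
#' @param object a [CongenerSpec-class] object.
#' @return Character scalar in the `"Cn[:d]-Cm[:e]"` grammar, shorter chain
#'   first; the `:d` suffix appears only for unsaturated chains.
#' @examples
#' canonicalName(congenerSpec(chainSpec(14, 1), chainSpec(13)))
#' @export
setGeneric("canonicalName", function(object) standardGeneric("canonicalName"))

#' Total carbon count of a congener
#' @param object a [CongenerSpec-class] object.
#' @return Integer: sum of the two chain lengths.
#' @export
setGeneric("totalCarbons", function(object) standardGeneric("totalCarbons"))

#' Total unsaturation count of a congener
#' @param object a [CongenerSpec-class] object.
#' @return Integer: sum of the two chains' double-bond counts.
#' @export
setGeneric("totalUnsaturations", function(object) standardGeneric("totalUnsaturations"))

#' Predicted ester-cleavage fragment m/z values
#'
#' Collision-induced dissociation of a deprotonated HAA is dominated by
#' cleavage of the ester bond, releasing each constituent 3-hydroxy fatty
#' acid as its deprotonated free acid.
#'
#' @param object a [CongenerSpec-class] object.
#' @param digits as in [mzDeprotonated()].
#' @return Numeric vector of fragment m/z values, ascending; a single value
#'   when the two chains are identical.
#' @export
setGeneric("predictFragments", function(object, digits = NA) standardGeneric("predictFragments"))

#' Precursor m/z accessor
#' @param object a [Spectrum-class] object.
#' @return Numeric scalar.
#' @export
setGeneric("precursorMz", function(object) standardGeneric("precursorMz"))

#' Fragment peak list accessor
#' @param object a [Spectrum-class] object.
#' @return `data.frame` with columns `mz` and `intensity`, sorted by m/z.
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))

#' Congener fractions of a profile
#' @param object a [CongenerProfile-class] object.
#' @return Named numeric vector: canonical congener name -> fraction (%).
#' @export
setGeneric("fractions", function(object) standardGeneric("fractions"))

#' Abundance-weighted average chain length of a congener profile
#'
#' The fraction-weighted mean of the per-molecule mean chain length
#' (n + m)/2, a standard one-number summary of an HAA congener spectrum.
#'
#' @param object a [CongenerProfile-class] object (non-empty).
#' @return Numeric scalar in carbon atoms (full precision; round to 1
#'   decimal for reporting).
#' @examples
#' averageChainLength(referenceProfiles()[["pPA2"]])
#' @export
setGeneric("averageChainLength", function(object) standardGeneric("averageChainLength"))

#' Neighborhood feature table accessor
#' @param object a [GeneNeighborhood-class] object.
#' @return `data.frame` with columns `id`, `label`, `strand`, `ordinal`.
#' @export
setGeneric("features", function(object) standardGeneric("features"))

#' Classify an acyltransferase candidate locus by gene synteny
#'
#' rhlA loci sit in glycolipid synthesis operons (with rhlB, or with
#' rhlC/transporter genes), whereas phaG loci sit in a conserved context of
#' uracil-DNA glycosylase, 3-hydroxyisobutyryl-CoA hydrolase and RsuA genes
#' upstream and a tRNA gene downstream. This difference is applied as an
#' ordered rule list.
#'
#' @param object a [GeneNeighborhood-class] object with exactly one
#'   `rhlA_candidate` feature.
#' @return A list with elements `classification` (one of
#'   `"rhlA_glycolipid_operon"`, `"rhlA_transporter_synteny"`, `"phaG"`,
#'   `"unsupported"`), `rule` (the index of the fired rule) and `trace`
#'   (character description of the evidence).
#' @examples
#' classifyLocus(generateNeighborhood("rhlAB_operon"))
#' @export
setGeneric("classifyLocus", function(object) standardGeneric("classifyLocus"))
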