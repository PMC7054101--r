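# Synthetic inputs for every pipeline stage: congener profiles, ESI(-)
# MS/MS spectra, GC-EI peak lists and toy gene neighborhoods, with
# controlled noise so each stage is testable without instrument data.

#' Configuration for the synthetic-data generators
#'
#' The defaults emulate the measurement setting the pipeline targets: a
#' high-resolution negative-mode instrument with about 1 ppm mass error
#' (comfortably inside the 5 ppm accuracy criterion), multiplicative
#' (log-normal) intensity noise, every ester-cleavage fragment detected,
#' and no co-eluting free-fatty-acid interferents.
#'
#' @param profile a plasmid name from the packaged dataset (`"pPA2"` ...
#'   `"pBUG"`), a named numeric congener -> fraction map, or `"random"`
#'   for a Dirichlet-like draw over `congenerSet`.
#' @param massErrorPpm Gaussian mass error sigma in ppm (default 1).
#' @param intensitySdLog log-normal sigma of intensity noise (default
#'   0.3).
#' @param fragmentDetectionProb probability each predicted fragment is
#'   observed (default 1).
#' @param interferents number of free-fatty-acid interferent peaks added
#'   per spectrum (default 0).
#' @param congenerSet canonical names for random profiles (default: the
#'   packaged reference congeners).
#' @param seed integer seed; mandatory for any stochastic generation.
#' @return A validated list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(profile = "pPA2", massErrorPpm = 1.0,
                            intensitySdLog = 0.3, fragmentDetectionProb = 1.0,
                            interferents = 0L, congenerSet = NULL,
                            seed = NULL) {
    stopifnot(massErrorPpm >= 0, intensitySdLog >= 0,
              fragmentDetectionProb >= 0, fragmentDetectionProb <= 1,
              interferents >= 0)
    stochastic <- massErrorPpm > 0 || intensitySdLog > 0 ||
        fragmentDetectionProb < 1 || interferents > 0 ||
        identical(profile, "random")
    if (stochastic && is.null(seed))
        stop("a seed is mandatory for stochastic generation")
    structure(list(profile = profile, massErrorPpm = massErrorPpm,
                   intensitySdLog = intensitySdLog,
                   fragmentDetectionProb = fragmentDetectionProb,
                   interferents = as.integer(interferents),
                   congenerSet = congenerSet,
                   seed = if (is.null(seed)) NULL else as.integer(seed)),
              class = "SyntheticConfig")
}

#' Generate a congener profile
#'
#' Fixture mode (`profile` names a plasmid) reproduces the packaged
#' column exactly; map mode uses the supplied fractions; random mode
#' draws a Dirichlet(1,...,1) composition over the configured congener
#' set. Provenance is always `"synthetic"`.
#'
#' @param cfg a [syntheticConfig()] object.
#' @return A [CongenerProfile-class] object.
#' @examples
#' generateProfile(syntheticConfig("pPA2"))
#' @export
generateProfile <- function(cfg = syntheticConfig()) {
    stopifnot(inherits(cfg, "SyntheticConfig"))
    pr <- cfg$profile
    if (is.numeric(pr)) {
        p <- congenerProfile(pr, label = "custom", provenance = "synthetic")
    } else if (identical(pr, "random")) {
        set.seed(cfg$seed)
        set <- cfg$congenerSet
        if (is.null(set)) set <- referenceCongeners()
        g <- stats::rgamma(length(set), shape = 1)   # flat Dirichlet
        p <- congenerProfile(structure(g / sum(g) * 100, names = set),
                             label = "random", provenance = "synthetic")
    } else {
        fix <- referenceProfiles(pr)[[1]]   # errors listing columns if unknown
        p <- congenerProfile(fractions(fix), label = pr, provenance = "synthetic")
    }
    p
}

.perturbPpm <- function(mz, sigmaPpm) {
    if (sigmaPpm <= 0) return(mz)
    mz * (1 + stats::rnorm(length(mz), 0, sigmaPpm) * 1e-6)
}

#' Generate one MS/MS spectrum per congener of a profile
#'
#' For each congener: the precursor is the theoretical [M-H]- of the
#' intact HAA and the fragments are the chain [M-H]- values, each
#' perturbed by Gaussian ppm error; fragment intensities are proportional
#' to the congener fraction with log-normal noise; each fragment is kept
#' with the configured detection probability. Optional interferent peaks
#' are placed at deprotonated free-fatty-acid masses. The LC dimension
#' separates congeners, hence one spectrum per congener; co-elution can
#' be emulated with [mergeSpectra()].
#'
#' @param p a [CongenerProfile-class] object (default: generated from
#'   `cfg`).
#' @param cfg a [syntheticConfig()] object.
#' @return List of [Spectrum-class] objects, named and id'd by congener.
#' @examples
#' s <- generateMsmsSpectra(cfg = syntheticConfig("pPA2", massErrorPpm = 0))
#' precursorMz(s[["C10-C10"]])
#' @export
generateMsmsSpectra <- function(p = generateProfile(cfg), cfg = syntheticConfig()) {
    stopifnot(inherits(cfg, "SyntheticConfig"), is(p, "CongenerProfile"))
    if (!is.null(cfg$seed)) set.seed(cfg$seed)
    out <- lapply(names(fractions(p)), function(nm) {
        cg <- parseCongener(nm)
        frac <- fractions(p)[[nm]]
        prec <- .perturbPpm(mzDeprotonated(.congenerFormula(cg)), cfg$massErrorPpm)
        theo <- predictFragments(cg)
        keep <- stats::runif(length(theo)) <= cfg$fragmentDetectionProb
        fmz <- .perturbPpm(theo[keep], cfg$massErrorPpm)
        base <- 1e4 * max(frac, 0.01) / 100
        intens <- base * stats::rlnorm(length(fmz), 0, cfg$intensitySdLog)
        if (cfg$interferents > 0L) {
            ns <- sample(8:18, cfg$interferents, replace = TRUE)
            ds <- sample(0:1, cfg$interferents, replace = TRUE)
            imz <- vapply(seq_len(cfg$interferents), function(i)
                mzDeprotonated(molecularFormula(C = ns[i], H = 2L * ns[i] - 2L * ds[i],
                                                O = 2L)), numeric(1))
            fmz <- c(fmz, .perturbPpm(imz, cfg$massErrorPpm))
            intens <- c(intens, base * 0.1 * stats::rlnorm(cfg$interferents, 0,
                                                           cfg$intensitySdLog))
        }
        msSpectrum(prec, data.frame(mz = fmz, intensity = intens), id = nm)
    })
    names(out) <- names(fractions(p))
    out
}

#' Merge spectra to emulate co-eluting congeners
#'
#' @param spectra list of [Spectrum-class] objects sharing (approximately)
#'   one precursor; the merged precursor is their mean.
#' @param id identifier for the merged spectrum.
#' @return A single [Spectrum-class] object containing all peaks.
#' @export
mergeSpectra <- function(spectra, id = "merged") {
    stopifnot(length(spectra) >= 1L)
    pk <- do.call(rbind, lapply(spectra, peaks))
    msSpectrum(mean(vapply(spectra, precursorMz, numeric(1))), pk, id = id)
}

#' Generate a GC-EI peak list for a known chain
#'
#' Peaks at the [M-15]+ chain-length ion and the hydroxy-position
#' diagnostic, with uniform m/z jitter and optional uniform background
#' peaks in the EI scan range (m/z 50-500).
#'
#' @param chain a [ChainSpec-class] object.
#' @param jitterDa maximal absolute m/z jitter (uniform in
#'   `[-jitterDa, jitterDa]`; default 0.2; 0 for exact peaks).
#' @param background number of uniform background peaks (default 0).
#' @param seed integer seed (mandatory when jitter or background is
#'   active).
#' @return `data.frame` with columns `mz`, `intensity`.
#' @examples
#' generateEiPeaklist(chainSpec(13), jitterDa = 0)   # peaks 301 and 175
#' @export
generateEiPeaklist <- function(chain, jitterDa = 0.2, background = 0L, seed = NULL) {
    stopifnot(is(chain, "ChainSpec"), jitterDa >= 0, background >= 0)
    if ((jitterDa > 0 || background > 0) && is.null(seed))
        stop("a seed is mandatory for stochastic generation")
    if (!is.null(seed)) set.seed(seed)
    mz <- as.numeric(c(mMinus15(chain), positionDiagnosticMz(chain@hydroxylPosition)))
    if (jitterDa > 0)
        mz <- mz + stats::runif(length(mz), -jitterDa, jitterDa)
    intensity <- c(100, 60)
    if (background > 0L) {
        mz <- c(mz, stats::runif(background, 50, 500))
        intensity <- c(intensity, stats::runif(background, 1, 20))
    }
    out <- data.frame(mz = mz, intensity = intensity)
    out <- out[order(out$mz), , drop = FALSE]
    rownames(out) <- NULL
    out
}

.NEIGHBORHOOD_LAYOUTS <- list(
    # glycolipid operon: rhlAB colocalized with the quorum-sensing
    # regulator/inducer pair, all co-oriented
    rhlAB_operon = data.frame(
        id = c("geneL1", "rhlA", "rhlB", "rhlR", "rhlI", "geneR1"),
        label = c("other", "rhlA_candidate", "rhlB", "rhlR", "rhlI", "other"),
        strand = c("-", "+", "+", "+", "+", "+"),
        product = c("conserved protein", "HAA synthase candidate",
                    "rhamnosyltransferase 1", "transcriptional regulator RhlR",
                    "autoinducer synthase RhlI", "conserved protein"),
        stringsAsFactors = FALSE),
    # candidate in synteny with a putative transporter, no rhlB
    rhlA_transporter = data.frame(
        id = c("geneL1", "rhlA", "tpt", "geneR1"),
        label = c("other", "rhlA_candidate", "transporter", "other"),
        strand = c("+", "+", "+", "-"),
        product = c("conserved protein", "HAA synthase candidate",
                    "putative transporter", "conserved protein"),
        stringsAsFactors = FALSE),
    # conserved phaG context: UDG, 3-HIB-CoA hydrolase, unknown-function
    # gene and RsuA upstream, tRNA downstream
    phaG_context = data.frame(
        id = c("udg", "hibch", "uf", "rsuA", "phaG", "trna"),
        label = c("UDG", "HIB_CoA_hydrolase", "unknown_function", "RsuA",
                  "rhlA_candidate", "tRNA"),
        strand = c("+", "+", "+", "+", "+", "+"),
        product = c("uracil-DNA glycosylase", "3-hydroxyisobutyryl-CoA hydrolase",
                    "protein of unknown function",
                    "ribosomal small subunit pseudouridine synthase A",
                    "transacylase candidate", "tRNA-Gly"),
        stringsAsFactors = FALSE),
    # candidate with no informative neighbors
    isolated = data.frame(
        id = c("geneL2", "geneL1", "rhlA", "geneR1", "geneR2"),
        label = c("other", "other", "rhlA_candidate", "other", "other"),
        strand = c("+", "-", "+", "+", "-"),
        product = c("conserved protein", "conserved protein",
                    "HAA synthase candidate", "conserved protein",
                    "conserved protein"),
        stringsAsFactors = FALSE)
)

#' Generate a toy gene neighborhood of a named layout
#'
#' Deterministic toy loci matching the synteny patterns the classifier is
#' built on; [classifyLocus()] on each layout returns the corresponding
#' class (`rhlAB_operon` -> `rhlA_glycolipid_operon`, `rhlA_transporter`
#' -> `rhlA_transporter_synteny`, `phaG_context` -> `phaG`, `isolated` ->
#' `unsupported`).
#'
#' @param kind layout name.
#' @param seed accepted for interface symmetry with the other generators;
#'   the layouts are deterministic.
#' @param gffPath optional path; when given, the neighborhood is also
#'   written as a GFF3 file (via `rtracklayer`) that [readNeighborhood()]
#'   reads back.
#' @param window classifier window (default 5).
#' @return A [GeneNeighborhood-class] object; the candidate feature id is
#'   `"rhlA"` (`"phaG"` for the phaG layout).
#' @examples
#' classifyLocus(generateNeighborhood("phaG_context"))$classification
#' @export
generateNeighborhood <- function(kind = c("rhlAB_operon", "rhlA_transporter",
                                          "phaG_context", "isolated"),
                                 seed = NULL, gffPath = NULL, window = 5L) {
    kind <- match.arg(kind)
    layout <- .NEIGHBORHOOD_LAYOUTS[[kind]]
    layout$ordinal <- seq_len(nrow(layout))
    if (!is.null(gffPath)) {
        width <- 900L
        gap <- 100L
        gr <- GenomicRanges::GRanges(
            seqnames = "toy_locus",
            ranges = IRanges::IRanges(
                start = (layout$ordinal - 1L) * (width + gap) + 1L,
                width = width),
            strand = layout$strand)
        gr$type <- "gene"
        gr$ID <- layout$id
        gr$Name <- layout$id
        gr$product <- layout$product
        rtracklayer::export(gr, gffPath, format = "gff3")
    }
    geneNeighborhood(layout[, c("id", "label", "strand", "ordinal")], window = window)
}
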