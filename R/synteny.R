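# Rule-based classification of acyltransferase candidate loci as rhlA-like
# or phaG-like from their gene neighborhoods.

#' Controlled vocabulary of neighborhood feature labels
#'
#' @return Character vector of the functional labels the classifier
#'   understands.
#' @export
featureLabels <- function() .FEATURE_LABELS

#' Construct a gene neighborhood
#'
#' @param features `data.frame` with columns `id`, `label` (see
#'   [featureLabels()]), `strand` (`"+"`/`"-"`) and `ordinal` (unique
#'   integer gene order); exactly one row must carry the label
#'   `rhlA_candidate`.
#' @param window genes up/downstream the classifier may consult
#'   (default 5; published operon figures show at most five relevant
#'   flanking genes).
#' @return A [GeneNeighborhood-class] object (features sorted by ordinal).
#' @export
geneNeighborhood <- function(features, window = 5L) {
    features <- as.data.frame(features)
    features <- features[order(features$ordinal), , drop = FALSE]
    features$id <- as.character(features$id)
    features$label <- as.character(features$label)
    features$strand <- as.character(features$strand)
    features$ordinal <- as.integer(features$ordinal)
    rownames(features) <- NULL
    new("GeneNeighborhood", features = features, window = as.integer(window))
}

#' @describeIn geneNeighborhood feature table accessor.
#' @param object a [GeneNeighborhood-class] object.
#' @export
setMethod("features", "GeneNeighborhood", function(object) object@features)

setMethod("show", "GeneNeighborhood", function(object) {
    ft <- object@features
    cand <- ft$label == "rhlA_candidate"
    lab <- ifelse(cand, paste0("[", ft$label, "]"), ft$label)
    cat(sprintf("GeneNeighborhood: %d feature(s), window %d\n  %s\n",
                nrow(ft), object@window,
                paste(sprintf("%s(%s)", lab, ft$strand), collapse = " - ")))
})

#' @describeIn classifyLocus ordered rule evaluation; exactly one rule
#'   fires.
#' @export
setMethod("classifyLocus", "GeneNeighborhood", function(object) {
    validObject(object)
    ft <- object@features
    cand <- ft[ft$label == "rhlA_candidate", ]
    w <- object@window
    near <- ft[ft$label != "rhlA_candidate" &
               abs(ft$ordinal - cand$ordinal) <= w, , drop = FALSE]
    # upstream/downstream are strand-aware relative to the candidate
    if (cand$strand == "+") {
        up <- near[near$ordinal < cand$ordinal, , drop = FALSE]
        down <- near[near$ordinal > cand$ordinal, , drop = FALSE]
    } else {
        up <- near[near$ordinal > cand$ordinal, , drop = FALSE]
        down <- near[near$ordinal < cand$ordinal, , drop = FALSE]
    }
    hasRhlB <- any(near$label == "rhlB")
    # Rule 1: rhlB in the window on the same strand -> glycolipid operon.
    sameStrandRhlB <- near$label == "rhlB" & near$strand == cand$strand
    if (any(sameStrandRhlB)) {
        ids <- near$id[sameStrandRhlB]
        return(list(classification = "rhlA_glycolipid_operon", rule = 1L,
                    trace = sprintf("rhlB (%s) within %d genes on the same strand",
                                    paste(ids, collapse = ","), w)))
    }
    # Rule 2: rhlC or a transporter nearby without any rhlB.
    aux <- near$label %in% c("rhlC", "transporter")
    if (any(aux) && !hasRhlB) {
        ids <- near$id[aux]
        return(list(classification = "rhlA_transporter_synteny", rule = 2L,
                    trace = sprintf("rhlC/transporter (%s) within %d genes, no rhlB",
                                    paste(ids, collapse = ","), w)))
    }
    # Rule 3: the conserved phaG context (UDG + 3-HIB-CoA hydrolase + RsuA
    # upstream, tRNA downstream).
    phaGUp <- c("UDG", "HIB_CoA_hydrolase", "RsuA")
    if (all(phaGUp %in% up$label) && "tRNA" %in% down$label) {
        return(list(classification = "phaG", rule = 3L,
                    trace = sprintf("upstream %s; tRNA downstream",
                                    paste(intersect(up$label, c(phaGUp, "unknown_function")),
                                          collapse = ","))))
    }
    list(classification = "unsupported", rule = 4L,
         trace = "no glycolipid-operon or phaG synteny evidence in the window")
})

#' Default product-string to label synonym table
#'
#' Case-insensitive regular expressions mapping free-text gene product
#' annotations onto the classifier's controlled vocabulary. The mapping is
#' configuration, not code: extend or replace it via the `synonyms`
#' argument of [readNeighborhood()].
#'
#' @return Named character vector: regex -> label.
#' @export
defaultSynonymTable <- function() {
    c("rhamnosyltransferase ?(1|I\\b)|\\brhlB\\b"        = "rhlB",
      "rhamnosyltransferase ?(2|II\\b)|\\brhlC\\b"       = "rhlC",
      "\\brhlR\\b|transcriptional regulator"             = "rhlR",
      "\\brhlI\\b|autoinducer synth"                     = "rhlI",
      "transporter|efflux|permease"                      = "transporter",
      "\\bnodT\\b"                                       = "nodT",
      "\\bhylD\\b|\\bhlyD\\b"                            = "hylD",
      "methyl ?transferase"                              = "methyltransferase",
      "uracil-? ?DNA glycosylase|\\bUDG\\b"              = "UDG",
      "hydroxyisobutyryl-? ?CoA hydrolase|3-?HIB"        = "HIB_CoA_hydrolase",
      "pseudouridine|\\bRsuA\\b"                         = "RsuA",
      "\\btRNA\\b"                                       = "tRNA",
      "unknown function|hypothetical"                    = "unknown_function",
      "conserved protein|uncharacterized"                = "other")
}

.mapProductLabel <- function(product, synonyms) {
    for (i in seq_along(synonyms)) {
        if (grepl(names(synonyms)[i], product, ignore.case = TRUE, perl = TRUE))
            return(unname(synonyms[i]))
    }
    NA_character_
}

#' Load a gene neighborhood from GFF3 or TSV
#'
#' GFF3 files (read with `rtracklayer`) contribute their gene/CDS features
#' ordered by start coordinate; product (or Name) attributes are mapped
#' onto the controlled vocabulary through the synonym table, unmappable
#' products become `"other"` with a warning. TSV files carry the four
#' columns `id`, `product`, `strand`, `ordinal` directly. The feature
#' whose `id` (GFF: ID/Name/locus_tag) equals `candidateId` becomes the
#' `rhlA_candidate`; its absence is an error.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or tab-separated file.
#' @param candidateId identifier of the acyltransferase candidate gene.
#' @param window classifier window (default 5).
#' @param synonyms regex -> label map (default [defaultSynonymTable()]).
#' @return A [GeneNeighborhood-class] object centered on the candidate
#'   (features beyond the window are dropped).
#' @export
readNeighborhood <- function(path, candidateId, window = 5L,
                             synonyms = defaultSynonymTable()) {
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path))
    if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
        gr <- rtracklayer::import(path)
        gr <- gr[as.character(gr$type) %in% c("gene", "CDS")]
        gr <- gr[order(GenomicRanges::start(gr))]
        meta <- S4Vectors::mcols(gr)
        getcol <- function(col) if (col %in% names(meta))
            as.character(meta[[col]]) else rep(NA_character_, length(gr))
        ids <- getcol("ID")
        ids <- ifelse(is.na(ids), getcol("Name"), ids)
        ids <- ifelse(is.na(ids), getcol("locus_tag"), ids)
        ids <- ifelse(is.na(ids), sprintf("feature%02d", seq_along(gr)), ids)
        product <- getcol("product")
        product <- ifelse(is.na(product), getcol("Name"), product)
        tab <- data.frame(id = ids,
                          product = ifelse(is.na(product), "", product),
                          strand = as.character(GenomicRanges::strand(gr)),
                          ordinal = seq_along(gr),
                          stringsAsFactors = FALSE)
        tab$strand[!tab$strand %in% c("+", "-")] <- "+"
    } else {
        tab <- utils::read.delim(path, stringsAsFactors = FALSE)
        need <- c("id", "product", "strand", "ordinal")
        if (!all(need %in% names(tab)))
            stop(sprintf("TSV neighborhood must have columns %s",
                         paste(need, collapse = ", ")))
    }
    if (!candidateId %in% tab$id)
        stop(sprintf("candidate '%s' not found in %s", candidateId, path))
    lab <- vapply(tab$product, .mapProductLabel, character(1), synonyms = synonyms)
    unmapped <- is.na(lab) & tab$id != candidateId
    if (any(unmapped))
        warning(sprintf("unmappable product label(s) set to 'other': %s",
                        paste(unique(tab$product[unmapped]), collapse = "; ")))
    lab[is.na(lab)] <- "other"
    lab[tab$id == candidateId] <- "rhlA_candidate"
    tab$label <- lab
    candOrd <- tab$ordinal[tab$id == candidateId]
    tab <- tab[abs(tab$ordinal - candOrd) <= window, , drop = FALSE]
    geneNeighborhood(tab[, c("id", "label", "strand", "ordinal")], window = window)
}
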