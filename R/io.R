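# File-format adapters: MGF and CSV peak lists, profile and report CSVs.
# All writers are deterministic for identical inputs (no timestamps).

#' Read MS/MS spectra from MGF or CSV
#'
#' MGF files use the minimal dialect `BEGIN IONS` / `TITLE=` / `PEPMASS=`
#' / `RTINSECONDS=` / one `mz intensity` pair per line / `END IONS`
#' (there is no maintained R MGF reader, so the dialect is parsed here,
#' with line numbers in every diagnostic). CSV files carry the columns
#' `spectrum_id`, `precursor_mz`, `fragment_mz`, `intensity`, one row per
#' fragment peak.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"mgf"` or `"csv"`.
#' @return List of [Spectrum-class] objects.
#' @seealso [writeSpectra()]
#' @export
readSpectra <- function(path, format = c("auto", "mgf", "csv")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path))
    if (format == "auto")
        format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf" else "csv"
    if (format == "mgf") .readMgf(path) else .readSpectraCsv(path)
}

.readMgf <- function(path) {
    lines <- readLines(path)
    out <- list()
    inBlock <- FALSE
    prec <- NA_real_; id <- ""; rt <- NA_real_
    mz <- numeric(); intensity <- numeric()
    startLine <- 0L
    for (i in seq_along(lines)) {
        ln <- trimws(lines[i])
        if (!nzchar(ln) || startsWith(ln, "#")) next
        if (ln == "BEGIN IONS") {
            if (inBlock)
                stop(sprintf("%s:%d: BEGIN IONS inside an open block (opened at line %d)",
                             path, i, startLine))
            inBlock <- TRUE; startLine <- i
            prec <- NA_real_; id <- ""; rt <- NA_real_
            mz <- numeric(); intensity <- numeric()
        } else if (ln == "END IONS") {
            if (!inBlock)
                stop(sprintf("%s:%d: END IONS without BEGIN IONS", path, i))
            if (is.na(prec))
                stop(sprintf("%s:%d: block starting at line %d has no PEPMASS",
                             path, i, startLine))
            out[[length(out) + 1L]] <-
                msSpectrum(prec, data.frame(mz = mz, intensity = intensity),
                           id = id, rt = rt)
            inBlock <- FALSE
        } else if (inBlock && grepl("=", ln, fixed = TRUE)) {
            key <- toupper(sub("=.*$", "", ln))
            val <- sub("^[^=]*=", "", ln)
            if (key == "PEPMASS") prec <- as.numeric(strsplit(val, "[ \t]+")[[1]][1])
            else if (key == "TITLE") id <- val
            else if (key == "RTINSECONDS") rt <- as.numeric(val)
            # other headers are ignored
        } else if (inBlock) {
            pair <- suppressWarnings(as.numeric(strsplit(ln, "[ \t]+")[[1]]))
            if (length(pair) < 2L || any(is.na(pair[1:2])))
                stop(sprintf("%s:%d: malformed peak line '%s'", path, i, ln))
            mz <- c(mz, pair[1]); intensity <- c(intensity, pair[2])
        } else {
            stop(sprintf("%s:%d: content outside BEGIN IONS/END IONS: '%s'", path, i, ln))
        }
    }
    if (inBlock)
        stop(sprintf("%s: block starting at line %d is not closed by END IONS",
                     path, startLine))
    out
}

.readSpectraCsv <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("spectrum_id", "precursor_mz", "fragment_mz", "intensity")
    missing <- setdiff(need, names(tab))
    if (length(missing))
        stop(sprintf("%s: missing column(s) %s", path, paste(missing, collapse = ", ")))
    out <- lapply(split(tab, tab$spectrum_id), function(block) {
        prec <- unique(block$precursor_mz)
        if (length(prec) != 1L)
            stop(sprintf("%s: spectrum '%s' has inconsistent precursor_mz",
                         path, block$spectrum_id[1]))
        keep <- !is.na(block$fragment_mz)
        msSpectrum(prec, data.frame(mz = block$fragment_mz[keep],
                                    intensity = block$intensity[keep]),
                   id = as.character(block$spectrum_id[1]))
    })
    out[order(vapply(out, spectrumId, character(1)))]
}

#' Write spectra as MGF
#'
#' @param spectra list of [Spectrum-class] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(spectra, path) {
    if (is(spectra, "Spectrum")) spectra <- list(spectra)
    blocks <- vapply(spectra, function(s) {
        pk <- peaks(s)
        paste(c("BEGIN IONS",
                if (nzchar(spectrumId(s))) sprintf("TITLE=%s", spectrumId(s)),
                sprintf("PEPMASS=%.6f", precursorMz(s)),
                if (!is.na(s@rt)) sprintf("RTINSECONDS=%.3f", s@rt),
                if (nrow(pk)) sprintf("%.6f %.4f", pk$mz, pk$intensity),
                "END IONS"),
              collapse = "\n")
    }, character(1))
    writeLines(paste(blocks, collapse = "\n\n"), path)
    invisible(path)
}

#' Read a congener profile from CSV
#'
#' Expects the two columns `congener` (canonical names, any chain order)
#' and `fraction_percent`. Duplicate congeners (after canonicalization)
#' and unparseable names are errors carrying the offending row number.
#'
#' @param path input CSV.
#' @param label profile label (default: file name without extension).
#' @param provenance as in [congenerProfile()].
#' @return A [CongenerProfile-class] object.
#' @seealso [writeProfile()]
#' @export
readProfile <- function(path, label = sub("\\.[^.]*$", "", basename(path)),
                        provenance = "measured") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("congener", "fraction_percent")
    missing <- setdiff(need, names(tab))
    if (length(missing))
        stop(sprintf("%s: missing column(s) %s", path, paste(missing, collapse = ", ")))
    parsed <- lapply(seq_len(nrow(tab)), function(i) {
        cg <- try(parseCongener(tab$congener[i]), silent = TRUE)
        if (inherits(cg, "try-error"))
            stop(sprintf("%s row %d: unparseable congener name '%s'",
                         path, i, tab$congener[i]))
        cg
    })
    nm <- vapply(parsed, canonicalName, character(1))
    if (anyDuplicated(nm)) {
        i <- which(duplicated(nm))[1]
        stop(sprintf("%s row %d: duplicate congener '%s'", path, i, nm[i]))
    }
    congenerProfile(structure(tab$fraction_percent, names = nm),
                    label = label, provenance = provenance)
}

#' Write a congener profile as CSV
#'
#' @param p a [CongenerProfile-class] object.
#' @param path output CSV (columns `congener`, `fraction_percent`, stable
#'   order: descending fraction, then name).
#' @return `path`, invisibly.
#' @export
writeProfile <- function(p, path) {
    stopifnot(is(p, "CongenerProfile"))
    fr <- fractions(p)
    ord <- order(-fr, names(fr))
    utils::write.csv(data.frame(congener = names(fr)[ord],
                                fraction_percent = unname(fr)[ord]),
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write a profile report as CSV
#'
#' Serializes the table from [profileReport()] with a stable column order
#' and appends the profile-level statistics as comment lines, so
#' identical inputs yield byte-identical files.
#'
#' @param report a `data.frame` from [profileReport()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
    cols <- c("congener", "composition", "mz", "fraction", "novelty", "mainCongener")
    stopifnot(all(cols %in% names(report)))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# label: %s", attr(report, "label")),
                 sprintf("# average_chain_length: %.1f",
                         attr(report, "averageChainLength")),
                 sprintf("# odd_chain_share_percent: %.1f",
                         attr(report, "oddChainShare")),
                 sprintf("# odd_chain_share_novel_percent: %.1f",
                         attr(report, "oddChainShareNovel"))), con)
    utils::write.csv(report[, cols], con, row.names = FALSE, quote = FALSE)
    invisible(path)
}
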