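# File I/O: peak-table CSV, allele-frequency CSV, report JSON, run
# manifests. CSV dialect: comma-separated, UTF-8, header required,
# '.' decimal.

#' Write a peak table to CSV
#'
#' Schema: \code{sample_id,dye,size_bp,height_rfu}.
#'
#' @param table a \linkS4class{PeakTable}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writePeakTable <- function(table, path) {
    pk <- peaks(table)
    out <- data.frame(sample_id = rep(sampleID(table), nrow(pk)),
                      dye = pk$dye, size_bp = pk$size,
                      height_rfu = pk$height)
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    invisible(path)
}

#' Read a peak table from CSV
#'
#' Expects the \code{sample_id,dye,size_bp,height_rfu} schema written by
#' \code{\link{writePeakTable}}. Malformed rows are reported with file
#' name and line number.
#'
#' @param path CSV path.
#' @return a \linkS4class{PeakTable}.
#' @export
readPeakTable <- function(path) {
    if (!file.exists(path)) stop("peak table not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    need <- c("sample_id", "dye", "size_bp", "height_rfu")
    if (!all(need %in% names(df)))
        stop(path, ": missing column(s) ",
             paste(setdiff(need, names(df)), collapse = ", "))
    size <- suppressWarnings(as.numeric(df$size_bp))
    height <- suppressWarnings(as.numeric(df$height_rfu))
    bad <- which(is.na(size) | is.na(height) | !nzchar(df$dye))
    if (length(bad))
        stop(path, ": malformed row at line ", bad[1L] + 1L,
             " (non-numeric size/height or empty dye)")
    id <- unique(df$sample_id)
    if (length(id) > 1L)
        stop(path, ": more than one sample_id in a single peak table")
    if (!length(id)) id <- sub("\\.csv$", "", basename(path))
    PeakTable(id, data.frame(dye = df$dye, size = size, height = height),
              metadata = list(source = path))
}

#' Read an STR allele frequency table
#'
#' CSV with columns \code{locus,allele,freq}. A synthetic default is
#' bundled as \code{extdata/str_freqs_synthetic.csv} (invented
#' frequencies for the fixture ladder, not population data).
#'
#' @param path CSV path; defaults to the bundled synthetic table.
#' @return data.frame with columns \code{locus}, \code{allele},
#'   \code{freq}.
#' @export
readFrequencyTable <- function(path = system.file(
    "extdata", "str_freqs_synthetic.csv", package = "hfeRFLP",
    mustWork = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("locus", "allele", "freq")
    if (!all(need %in% names(df)))
        stop(path, ": frequency table needs columns locus,allele,freq")
    df$allele <- as.numeric(df$allele)
    df$freq <- as.numeric(df$freq)
    df
}

# ---- report serialization ----------------------------------------------

.reportToList <- function(report) {
    st <- report@control
    list(
        sample_id = report@sampleID,
        control = list(
            amplification_ok = st@amplificationOK,
            enzyme_status = as.list(st@enzymeStatus),
            evidence_sizes = st@evidence),
        marker_calls = lapply(report@markerCalls, function(mc) list(
            marker = mc@markerName, genotype = mc@genotype,
            reason = if (is.na(mc@reason)) NULL else mc@reason,
            supporting_peaks = mc@supportingPeaks[
                , intersect(c("dye", "size", "height"),
                            names(mc@supportingPeaks)), drop = FALSE])),
        str_calls = lapply(report@strCalls, function(sc) list(
            locus = sc@locusName, alleles = sc@alleles,
            peak_heights = sc@peakHeights,
            extra_alleles = sc@extraAlleles,
            off_ladder = sc@offLadder)),
        contamination = if (is(report@contamination, "ContaminationReport"))
            list(flagged = report@contamination@flagged,
                 evidence = report@contamination@evidence)
        else NULL)
}

#' Write one sample report as JSON
#'
#' @param report a \linkS4class{SampleReport}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeSampleReport <- function(report, path) {
    jsonlite::write_json(.reportToList(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
}

#' Render a sample report as human-readable text
#'
#' @param report a \linkS4class{SampleReport}.
#' @return character vector of lines.
#' @export
formatSampleReport <- function(report) {
    con <- textConnection("out", "w", local = TRUE)
    sink(con)
    show(report)
    sink()
    close(con)
    out
}

# ---- run manifest ------------------------------------------------------

#' Write a run manifest
#'
#' Every CLI run writes one manifest alongside its outputs: command,
#' panel file, seed, input/output paths, package version and timestamp —
#' enough to re-run the command.
#'
#' @param dir output directory.
#' @param command the subcommand executed.
#' @param args named list of arguments worth recording.
#' @return the manifest path, invisibly.
#' @export
writeRunManifest <- function(dir, command, args) {
    manifest <- list(
        command = command,
        args = args,
        package = "hfeRFLP",
        version = as.character(utils::packageVersion("hfeRFLP")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    path <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
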