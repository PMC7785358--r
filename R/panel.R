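# Assay panel configuration: YAML load/save, validation, channel
# separability.

.validationError <- function(msgs) {
    stop(structure(
        class = c("validationError", "error", "condition"),
        list(message = paste0("panel validation failed:\n",
                              paste0("  - ", msgs, collapse = "\n")),
             call = NULL)))
}

#' Load an assay panel from a YAML configuration
#'
#' Parses the documented panel schema, constructs every component with its
#' invariants checked, and additionally rejects panels whose expected
#' fragment sizes are not resolvable within their dye channels (see
#' \code{\link{validateChannelSeparability}}). All failed invariants are
#' reported together in a single \code{validationError}.
#'
#' @param path path to a panel YAML file.
#' @return a validated \linkS4class{AssayPanel}.
#' @seealso \code{\link{defaultPanel}} for the bundled HFE panel,
#'   \code{\link{writePanel}} for the inverse operation.
#' @examples
#' panel <- defaultPanel()
#' analyticalCutoff(panel)  # 250 RFU
#' @export
loadPanel <- function(path) {
    if (!file.exists(path))
        stop("panel config not found: ", path)
    cfg <- yaml::read_yaml(path)
    panel <- .panelFromList(cfg)
    conflicts <- validateChannelSeparability(panel)
    if (nrow(conflicts))
        .validationError(sprintf(
            "dye channel '%s': fragments '%s' (%g bp) and '%s' (%g bp) are within 1.0 bp",
            conflicts$dye, conflicts$fragment1, conflicts$size1,
            conflicts$fragment2, conflicts$size2))
    panel
}

.panelFromList <- function(cfg) {
    msgs <- character()
    need <- c("schema_version", "dyes", "enzymes", "primer_pairs",
              "rflp_markers", "str_loci", "control", "thresholds")
    missing <- setdiff(need, names(cfg))
    if (length(missing))
        .validationError(paste("missing config section(s):",
                               paste(missing, collapse = ", ")))

    capture <- function(expr) {
        tryCatch(expr, error = function(e) {
            msgs <<- c(msgs, conditionMessage(e))
            NULL
        })
    }
    enz <- lapply(cfg$enzymes, function(x)
        capture(Enzyme(x$name, x$recognition, x$cut_offset)))
    pp <- lapply(cfg$primer_pairs, function(x)
        capture(PrimerPair(x$marker, x$upper_seq, x$lower_seq,
                           x$upper_dye %||% NA_character_,
                           x$lower_dye %||% NA_character_)))
    mk <- lapply(cfg$rflp_markers, function(x)
        capture(RFLPMarker(x$name, x$enzyme, x$primer_pair,
                           x$amplicon_length, x$site_position,
                           x$variant_creates_site %||% TRUE,
                           x$labeled_end %||% "five_prime", x$dye)))
    loci <- lapply(cfg$str_loci, function(x)
        capture(STRLocus(x$name, x$repeat_unit_length, x$size_offset,
                         x$allele_min, x$allele_max, x$stutter_mean,
                         x$stutter_sd, x$dye)))
    ctl <- capture(with(cfg$control, ControlFragment(
        name, amplicon_length, sexai_site_start, bsphi_site_start,
        unlist(double_digest_sizes), unlist(single_failure_sizes),
        uncut_size, dye)))
    thc <- cfg$thresholds
    th <- capture({
        args <- list(noiseCeiling = thc$noise_ceiling,
                     cutoffMultiplier = thc$cutoff_multiplier,
                     saturation = thc$saturation,
                     stutterSDMultiplier = thc$stutter_sd_multiplier %||% 2)
        if (!is.null(thc$analytical_cutoff))
            args$analyticalCutoff <- thc$analytical_cutoff
        do.call(Thresholds, args)
    })
    if (length(msgs))
        .validationError(msgs)

    names(enz) <- vapply(enz, slot, character(1), "name")
    names(pp) <- vapply(pp, slot, character(1), "amplicon")
    names(mk) <- vapply(mk, slot, character(1), "name")
    names(loci) <- vapply(loci, slot, character(1), "name")
    tryCatch(
        new("AssayPanel", schemaVersion = as.integer(cfg$schema_version),
            dyes = as.character(cfg$dyes), enzymes = enz, primerPairs = pp,
            rflpMarkers = mk, strLoci = loci, control = ctl,
            thresholds = th),
        error = function(e) .validationError(conditionMessage(e)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an assay panel back to YAML
#'
#' The written document re-loads to a panel equal field-by-field to the
#' input (round trip).
#'
#' @param panel an \linkS4class{AssayPanel}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePanel <- function(panel, path) {
    th <- panel@thresholds
    cfg <- list(
        schema_version = panel@schemaVersion,
        dyes = panel@dyes,
        enzymes = lapply(unname(panel@enzymes), function(e)
            list(name = e@name, recognition = e@recognition,
                 cut_offset = e@cutOffset)),
        primer_pairs = lapply(unname(panel@primerPairs), function(p)
            list(marker = p@amplicon, upper_seq = p@upperSeq,
                 lower_seq = p@lowerSeq,
                 upper_dye = if (is.na(p@upperDye)) NULL else p@upperDye,
                 lower_dye = if (is.na(p@lowerDye)) NULL else p@lowerDye)),
        rflp_markers = lapply(unname(panel@rflpMarkers), function(m)
            list(name = m@name, enzyme = m@enzymeName,
                 primer_pair = m@primerPair,
                 amplicon_length = m@ampliconLength,
                 site_position = m@sitePosition,
                 variant_creates_site = m@variantCreatesSite,
                 labeled_end = m@labeledEnd, dye = m@dye)),
        str_loci = lapply(unname(panel@strLoci), function(l)
            list(name = l@name, repeat_unit_length = l@repeatUnitLength,
                 size_offset = l@sizeOffset, allele_min = l@alleleMin,
                 allele_max = l@alleleMax, stutter_mean = l@stutterMean,
                 stutter_sd = l@stutterSD, dye = l@dye)),
        control = list(
            name = panel@control@name,
            amplicon_length = panel@control@ampliconLength,
            sexai_site_start = panel@control@sexaiSiteStart,
            bsphi_site_start = panel@control@bsphiSiteStart,
            double_digest_sizes = as.list(panel@control@doubleDigestSizes),
            single_failure_sizes = as.list(panel@control@singleFailureSizes),
            uncut_size = panel@control@uncutSize,
            dye = panel@control@dye),
        thresholds = list(
            noise_ceiling = th@noiseCeiling,
            cutoff_multiplier = th@cutoffMultiplier,
            analytical_cutoff = th@analyticalCutoff,
            saturation = th@saturation,
            stutter_sd_multiplier = th@stutterSDMultiplier))
    yaml::write_yaml(cfg, path)
    invisible(path)
}

#' The bundled default HFE multiplex panel
#'
#' SexAI/BspHI enzymes, the five labeled primer pairs of the multiplex
#' (HFE exon 2 and 4, FGA, SE33, FZD1), the C282Y and H63D markers, the
#' FZD1 digestion control (114/147 bp double digest) and the default
#' thresholds (250 RFU cutoff = 5 x 50 RFU noise ceiling, 32000 RFU
#' saturation, mean + 2 SD stutter rule).
#'
#' @return a validated \linkS4class{AssayPanel}.
#' @export
defaultPanel <- function() {
    loadPanel(system.file("extdata", "hfe_panel.yaml", package = "hfeRFLP",
                          mustWork = TRUE))
}

#' Enumerate all fragment sizes a panel can produce, per dye
#'
#' Covers, per RFLP marker, the labeled cut size and the uncut amplicon;
#' for the control, the double-digest, single-failure and uncut sizes; for
#' each STR locus, the full allele ladder (integer repeats and
#' 2-bp microvariants within the allele range).
#'
#' @param panel an \linkS4class{AssayPanel}.
#' @return data.frame with columns \code{dye}, \code{size},
#'   \code{fragment}.
#' @export
expectedPanelSizes <- function(panel) {
    out <- list()
    for (m in panel@rflpMarkers) {
        out[[length(out) + 1L]] <- data.frame(
            dye = m@dye,
            size = c(.markerCutSize(panel, m), .markerUncutSize(m)),
            fragment = paste0(m@name, c(":cut", ":uncut")))
    }
    ctl <- panel@control
    out[[length(out) + 1L]] <- data.frame(
        dye = ctl@dye,
        size = c(unname(ctl@doubleDigestSizes), unname(ctl@singleFailureSizes),
                 ctl@uncutSize),
        fragment = c(paste0(ctl@name, ":", names(ctl@doubleDigestSizes),
                            "_digest"),
                     paste0(ctl@name, ":", names(ctl@singleFailureSizes),
                            "_failure"),
                     paste0(ctl@name, ":uncut")))
    for (l in panel@strLoci) {
        reps <- seq.int(floor(l@alleleMin), floor(l@alleleMax))
        des <- sort(c(reps, reps + 0.2))
        des <- des[des >= l@alleleMin - 1e-9 & des <= l@alleleMax + 1e-9]
        out[[length(out) + 1L]] <- data.frame(
            dye = l@dye, size = .strSize(l, des),
            fragment = paste0(l@name, ":", format(des, trim = TRUE)))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Report dye-channel size conflicts
#'
#' Two expected fragment sizes sharing a dye must differ by at least
#' 1.0 bp for the caller to resolve them (single-base capillary
#' resolution). Pairs belonging to the same STR allele ladder are by
#' construction at least 2 bp apart and never conflict.
#'
#' @param panel an \linkS4class{AssayPanel}.
#' @return a data.frame of conflicts (zero rows if the panel is
#'   separable) with columns \code{dye}, \code{fragment1}, \code{size1},
#'   \code{fragment2}, \code{size2}.
#' @examples
#' nrow(validateChannelSeparability(defaultPanel()))  # 0
#' @export
validateChannelSeparability <- function(panel) {
    sizes <- expectedPanelSizes(panel)
    res <- list()
    for (d in unique(sizes$dye)) {
        s <- sizes[sizes$dye == d, , drop = FALSE]
        if (nrow(s) < 2L) next
        s <- s[order(s$size), , drop = FALSE]
        for (i in seq_len(nrow(s) - 1L)) {
            j <- i + 1L
            while (j <= nrow(s) && s$size[j] - s$size[i] < 1.0 - 1e-9) {
                res[[length(res) + 1L]] <- data.frame(
                    dye = d, fragment1 = s$fragment[i], size1 = s$size[i],
                    fragment2 = s$fragment[j], size2 = s$size[j])
                j <- j + 1L
            }
        }
    }
    if (!length(res))
        return(data.frame(dye = character(), fragment1 = character(),
                          size1 = numeric(), fragment2 = character(),
                          size2 = numeric()))
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
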