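# Rule-based interpretation: analytical threshold, FZD1 digestion-control
# validation, RFLP genotype calls, STR allele calls.
#
# Size matching uses a +-1.0 bp tolerance everywhere (single-base
# capillary resolution); the height cutoff is inclusive (>=).

.SIZE_TOL <- 1.0

.matchesSize <- function(sizes, target) abs(sizes - target) <= .SIZE_TOL

#' Derive the analytical cutoff from blank runs
#'
#' Noise is measured as the highest background peak across the supplied
#' blank tables, rounded up to the nearest 10 RFU, and multiplied by the
#' cutoff multiplier: blanks peaking at 43.2 RFU with multiplier 5 give
#' \code{5 * 50 = 250} RFU.
#'
#' @param blankTables list of \linkS4class{PeakTable} from no-template
#'   runs.
#' @param multiplier cutoff multiplier (5 in the default panel).
#' @return the cutoff in RFU.
#' @export
deriveCutoff <- function(blankTables, multiplier) {
    if (!length(blankTables))
        stop("at least one blank table is required")
    heights <- unlist(lapply(blankTables, function(t) peaks(t)$height))
    if (!length(heights))
        stop("blank tables contain no peaks; cannot measure noise")
    multiplier * 10 * ceiling(max(heights) / 10)
}

#' Filter a peak table at a height cutoff
#'
#' Retains exactly the peaks with \code{height >= cutoff} (inclusive);
#' the input is unmodified.
#'
#' @param table a \linkS4class{PeakTable}.
#' @param cutoff height cutoff in RFU, > 0.
#' @return a new \linkS4class{PeakTable}.
#' @export
filterPeaks <- function(table, cutoff) {
    stopifnot(is(table, "PeakTable"), cutoff > 0)
    pk <- peaks(table)
    meta <- table@metadata
    meta$cutoff <- cutoff
    PeakTable(sampleID(table), pk[pk$height >= cutoff, , drop = FALSE], meta)
}

#' Validate the internal digestion controls
#'
#' An enzyme passes iff its expected double-digest control size
#' (+-1.0 bp) is present above the cutoff; it fails iff its configured
#' single-failure size or the uncut control size is present instead; with
#' no control-channel signal at all, amplification is failed and both
#' enzymes are indeterminate.
#'
#' @param table a \linkS4class{PeakTable} (raw or filtered).
#' @param panel an \linkS4class{AssayPanel}.
#' @param cutoff height cutoff in RFU.
#' @return a \linkS4class{ControlStatus}.
#' @export
checkDigestionControls <- function(table, panel,
                                   cutoff = analyticalCutoff(panel)) {
    ctl <- panel@control
    pk <- peaks(table)
    pk <- pk[pk$dye == ctl@dye & pk$height >= cutoff, , drop = FALSE]
    enzNames <- names(ctl@doubleDigestSizes)
    if (!nrow(pk))
        return(new("ControlStatus", amplificationOK = FALSE,
                   enzymeStatus = stats::setNames(
                       rep("indeterminate", length(enzNames)), enzNames),
                   evidence = numeric()))
    status <- character()
    evid <- numeric()
    for (e in enzNames) {
        ok <- any(.matchesSize(pk$size, ctl@doubleDigestSizes[[e]]))
        failSizes <- c(ctl@singleFailureSizes[[e]], ctl@uncutSize)
        failed <- any(outer(pk$size, failSizes, function(s, t)
            abs(s - t) <= .SIZE_TOL))
        status[[e]] <- if (ok) "pass" else if (failed) "fail"
                       else "indeterminate"
        evid <- c(evid, pk$size[.matchesSize(pk$size,
                                             ctl@doubleDigestSizes[[e]])])
    }
    new("ControlStatus", amplificationOK = TRUE, enzymeStatus = status,
        evidence = evid)
}

#' Call one RFLP marker
#'
#' The cut labeled size alone reads as a site-present homozygote, the
#' uncut size alone as a site-absent homozygote, both as a heterozygote;
#' site states map to reference/variant genotypes through the marker's
#' \code{variantCreatesSite} polarity. The call is gated on the digestion
#' control: if the marker's enzyme did not pass, the result is
#' \code{no_call} — never a potentially false homozygote.
#'
#' @param table a \linkS4class{PeakTable} filtered at \code{cutoff}.
#' @param marker an \linkS4class{RFLPMarker}.
#' @param control a \linkS4class{ControlStatus} for the same table.
#' @param cutoff height cutoff in RFU.
#' @param panel the panel (for enzyme cut offsets).
#' @return a \linkS4class{MarkerCall}.
#' @export
callMarker <- function(table, marker, control,
                       cutoff = analyticalCutoff(panel),
                       panel = defaultPanel()) {
    noCall <- function(reason)
        new("MarkerCall", markerName = marker@name, genotype = "no_call",
            supportingPeaks = data.frame(dye = character(),
                                         size = numeric(),
                                         height = numeric()),
            reason = reason)
    if (!control@amplificationOK)
        return(noCall("amplification_fail"))
    if (control@enzymeStatus[[marker@enzymeName]] != "pass")
        return(noCall("control_fail"))
    pk <- peaks(table)
    pk <- pk[pk$dye == marker@dye & pk$height >= cutoff, , drop = FALSE]
    cutSize <- .markerCutSize(panel, marker)
    uncutSize <- .markerUncutSize(marker)
    cutHit <- pk[.matchesSize(pk$size, cutSize), , drop = FALSE]
    uncutHit <- pk[.matchesSize(pk$size, uncutSize), , drop = FALSE]
    hasCut <- nrow(cutHit) > 0L
    hasUncut <- nrow(uncutHit) > 0L
    if (!hasCut && !hasUncut)
        return(noCall("no_peaks"))
    siteGeno <- if (hasCut && hasUncut) "het"
                else if (hasCut) "site_hom" else "nosite_hom"
    genotype <- if (siteGeno == "het") "het"
                else if ((siteGeno == "site_hom") == marker@variantCreatesSite)
                    "var_hom"
                else "ref_hom"
    new("MarkerCall", markerName = marker@name, genotype = genotype,
        supportingPeaks = rbind(cutHit, uncutHit), reason = NA_character_)
}

#' Call one STR locus
#'
#' Peaks in the locus's dye channel convert to allele designations via the
#' ladder \code{designation = (size - offset) / unit}, with any remainder
#' expressed as a microvariant decimal (remainder 2 bp gives x.2). Peaks
#' sitting exactly one repeat unit below a taller peak are classified as
#' stutter and excluded from allele status (they are the contamination
#' module's input). Of the surviving designations the two tallest are the
#' call; any further survivors are reported as \code{extraAlleles}.
#' Designations outside the locus range are recorded as off-ladder, never
#' an error.
#'
#' @param table a \linkS4class{PeakTable} filtered at \code{cutoff}.
#' @param locus an \linkS4class{STRLocus}.
#' @param cutoff height cutoff in RFU.
#' @return an \linkS4class{STRCall}.
#' @export
callSTR <- function(table, locus, cutoff) {
    pk <- peaks(table)
    pk <- pk[pk$dye == locus@dye & pk$height >= cutoff, , drop = FALSE]
    if (nrow(pk)) {
        pk$designation <- .strDesignation(locus, pk$size)
        onLadder <- pk$designation >= locus@alleleMin - 1e-9 &
            pk$designation <= locus@alleleMax + 1e-9
        offLadder <- pk$size[!onLadder]
        pk <- pk[onLadder, , drop = FALSE]
    } else {
        offLadder <- numeric()
    }
    if (!nrow(pk))
        return(new("STRCall", locusName = locus@name, alleles = numeric(),
                   peakHeights = numeric(), extraAlleles = numeric(),
                   extraHeights = numeric(), offLadder = offLadder))
    isStutter <- vapply(seq_len(nrow(pk)), function(i) {
        parent <- which(abs(pk$designation - (pk$designation[i] + 1)) < 1e-9)
        length(parent) > 0L && any(pk$height[parent] > pk$height[i])
    }, logical(1))
    cand <- pk[!isStutter, , drop = FALSE]
    cand <- cand[order(-cand$height, cand$designation), , drop = FALSE]
    nAllele <- min(2L, nrow(cand))
    called <- cand[seq_len(nAllele), , drop = FALSE]
    extra <- cand[-seq_len(nAllele), , drop = FALSE]
    # a homozygote is a single designation
    o <- order(called$designation)
    new("STRCall", locusName = locus@name,
        alleles = called$designation[o], peakHeights = called$height[o],
        extraAlleles = extra$designation, extraHeights = extra$height,
        offLadder = offLadder)
}

#' Genotype one sample end to end
#'
#' Applies, in order: peak filtering at the panel's analytical cutoff,
#' digestion-control validation, per-marker RFLP calls, STR calls.
#' Deterministic. The contamination slot is left empty; fill it with
#' \code{\link{detectContamination}}.
#'
#' @param table a raw \linkS4class{PeakTable}.
#' @param panel an \linkS4class{AssayPanel}.
#' @param cutoff height cutoff in RFU (panel default).
#' @return a \linkS4class{SampleReport}.
#' @examples
#' panel <- defaultPanel()
#' g <- makeGenotype(c282y = "var_hom", h63d = "het",
#'                   fga = c(20, 24), se33 = c(17, 29))
#' genotypeSample(simulateSample(panel, g, seed = 1), panel)
#' @export
genotypeSample <- function(table, panel, cutoff = analyticalCutoff(panel)) {
    filtered <- filterPeaks(table, cutoff)
    control <- checkDigestionControls(filtered, panel, cutoff)
    mcalls <- lapply(panel@rflpMarkers, function(m)
        callMarker(filtered, m, control, cutoff, panel))
    scalls <- lapply(panel@strLoci, function(l)
        callSTR(filtered, l, cutoff))
    new("SampleReport", sampleID = sampleID(table), control = control,
        markerCalls = mcalls, strCalls = scalls, contamination = NULL)
}
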