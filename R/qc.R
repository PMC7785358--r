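# Stutter statistics, contamination detection (extra STR alleles,
# elevated stutter, extra RFLP peaks), identity matching and match
# probability.

# ratios above this are a second allele hiding in the stutter bin, not
# polymerase slippage; they are excluded from calibration (but NOT from
# contamination evidence, where a huge ratio is exactly the signal)
.STUTTER_CALIBRATION_MAX <- 0.5

#' Estimate per-locus stutter statistics from single-source samples
#'
#' For every called allele whose one-repeat-shorter bin is not itself a
#' called allele, the stutter ratio is the height of the peak in that bin
#' (0 if absent, measured on the raw, unfiltered table) divided by the
#' allele peak height. Returns the sample mean and SD per locus. Ratios
#' above 0.5 are excluded as second alleles rather than slippage. A locus
#' with fewer than two usable ratios is marked unusable.
#'
#' @param tables list of raw \linkS4class{PeakTable} from samples assumed
#'   uncontaminated.
#' @param panel an \linkS4class{AssayPanel}.
#' @param cutoff height cutoff used to call parent alleles.
#' @return data.frame with one row per locus: \code{locus},
#'   \code{mean_ratio}, \code{sd_ratio}, \code{n_alleles}, \code{usable}.
#' @export
estimateStutterStats <- function(tables, panel,
                                 cutoff = analyticalCutoff(panel)) {
    ratios <- stats::setNames(
        replicate(length(panel@strLoci), numeric(), simplify = FALSE),
        names(panel@strLoci))
    for (tab in tables) {
        filtered <- filterPeaks(tab, cutoff)
        raw <- peaks(tab)
        for (l in panel@strLoci) {
            call <- callSTR(filtered, l, cutoff)
            des <- call@alleles
            if (!length(des)) next
            for (i in seq_along(des)) {
                d <- des[i]
                if (any(abs(des - (d - 1)) < 1e-9)) next  # allele in bin
                binSize <- .strSize(l, d - 1)
                hit <- raw$dye == l@dye &
                    abs(raw$size - binSize) <= .SIZE_TOL
                stutterH <- if (any(hit)) max(raw$height[hit]) else 0
                r <- stutterH / call@peakHeights[i]
                if (r <= .STUTTER_CALIBRATION_MAX)
                    ratios[[l@name]] <- c(ratios[[l@name]], r)
            }
        }
    }
    out <- data.frame(
        locus = names(ratios),
        mean_ratio = vapply(ratios, function(r)
            if (length(r) >= 2L) mean(r) else NA_real_, numeric(1)),
        sd_ratio = vapply(ratios, function(r)
            if (length(r) >= 2L) stats::sd(r) else NA_real_, numeric(1)),
        n_alleles = vapply(ratios, length, integer(1)))
    out$usable <- out$n_alleles >= 2L
    rownames(out) <- NULL
    out
}

#' Stutter contamination threshold (mean + k SD rule)
#'
#' Any stutter-position peak whose ratio to its parent allele exceeds
#' \code{mean + sdMultiplier * SD} is regarded as resulting from
#' contamination. With the assay's calibration values this is
#' \code{0.080 + 2 x 0.024 = 0.128} for FGA and
#' \code{0.106 + 2 x 0.024 = 0.154} for SE33.
#'
#' @param stats one row (or several) of
#'   \code{\link{estimateStutterStats}} output.
#' @param sdMultiplier the k of the rule (2 by default).
#' @return named numeric vector of threshold ratios, one per locus.
#' @export
stutterThreshold <- function(stats, sdMultiplier = 2) {
    if (any(!stats$usable))
        stop("unusable stutter statistics for locus/loci: ",
             paste(stats$locus[!stats$usable], collapse = ", "))
    stats::setNames(stats$mean_ratio + sdMultiplier * stats$sd_ratio,
                    stats$locus)
}

#' Detect inter-sample contamination in one sample
#'
#' Collects three kinds of evidence: (a) any STR locus with more than two
#' non-stutter designations above the cutoff (\code{extra_str_allele});
#' (b) any stutter-position peak whose ratio to its parent called allele
#' exceeds the locus's mean + k SD threshold (\code{elevated_stutter});
#' (c) any RFLP marker channel with more allele-state peaks (sizes
#' matching the panel's expected cut/uncut fragments within 1 bp) than one
#' genotype can explain (\code{extra_rflp_peak}). The sample is flagged on
#' any single finding.
#'
#' @param report the \linkS4class{SampleReport} produced from
#'   \code{table}.
#' @param table the raw \linkS4class{PeakTable}.
#' @param stats per-locus stutter statistics
#'   (\code{\link{estimateStutterStats}}), estimated from an independent
#'   uncontaminated cohort.
#' @param panel an \linkS4class{AssayPanel}.
#' @param cutoff height cutoff in RFU.
#' @param sdMultiplier the k of the stutter rule (panel default).
#' @return a \linkS4class{ContaminationReport}.
#' @export
detectContamination <- function(report, table, stats, panel,
                                cutoff = analyticalCutoff(panel),
                                sdMultiplier =
                                    panel@thresholds@stutterSDMultiplier) {
    ev <- list()
    addEv <- function(kind, locus, size, height, detail)
        ev[[length(ev) + 1L]] <<- data.frame(
            kind = kind, locus = locus, size = size, height = height,
            detail = detail)
    raw <- peaks(table)

    # (a) extra STR alleles
    for (sc in report@strCalls) {
        if (!length(sc@extraAlleles)) next
        l <- panel@strLoci[[sc@locusName]]
        for (i in seq_along(sc@extraAlleles))
            addEv("extra_str_allele", sc@locusName,
                  .strSize(l, sc@extraAlleles[i]), sc@extraHeights[i],
                  sprintf("allele %g beyond two", sc@extraAlleles[i]))
    }

    # (b) elevated stutter relative to called parent alleles
    for (sc in report@strCalls) {
        l <- panel@strLoci[[sc@locusName]]
        srow <- stats[stats$locus == sc@locusName, , drop = FALSE]
        if (!nrow(srow) || !srow$usable) {
            if (length(sc@alleles))
                warning("no usable stutter statistics for ", sc@locusName,
                        "; elevated-stutter rule skipped", call. = FALSE)
            next
        }
        thr <- stutterThreshold(srow, sdMultiplier)[[sc@locusName]]
        for (i in seq_along(sc@alleles)) {
            d <- sc@alleles[i]
            if (any(abs(sc@alleles - (d - 1)) < 1e-9)) next
            binSize <- .strSize(l, d - 1)
            hit <- raw$dye == l@dye & abs(raw$size - binSize) <= .SIZE_TOL
            if (!any(hit)) next
            h <- max(raw$height[hit])
            ratio <- h / sc@peakHeights[i]
            if (ratio > thr)
                addEv("elevated_stutter", sc@locusName, binSize, h,
                      sprintf("ratio %.3f above threshold %.3f at allele %g",
                              ratio, thr, d))
        }
    }

    # (c) surplus RFLP allele-state peaks in a marker channel
    for (m in panel@rflpMarkers) {
        pk <- raw[raw$dye == m@dye & raw$height >= cutoff, , drop = FALSE]
        if (!nrow(pk)) next
        sizes <- c(cut = .markerCutSize(panel, m),
                   uncut = .markerUncutSize(m))
        matched <- pk[.matchesSize(pk$size, sizes[["cut"]]) |
                      .matchesSize(pk$size, sizes[["uncut"]]), ,
                      drop = FALSE]
        if (nrow(matched) > 2L) {
            surplus <- matched[order(-matched$height), , drop = FALSE]
            surplus <- surplus[-(1:2), , drop = FALSE]
            for (i in seq_len(nrow(surplus)))
                addEv("extra_rflp_peak", m@name, surplus$size[i],
                      surplus$height[i],
                      "allele-state peak beyond one explicable genotype")
        }
    }

    evidence <- if (length(ev)) do.call(rbind, ev)
                else data.frame(kind = character(), locus = character(),
                                size = numeric(), height = numeric(),
                                detail = character())
    rownames(evidence) <- NULL
    new("ContaminationReport", flagged = nrow(evidence) > 0L,
        evidence = evidence)
}

#' Compare the STR identity profiles of two samples
#'
#' Two reports match iff their genotypes are equal at every shared locus.
#' The match probability is the chance that a random unrelated individual
#' shares the observed multi-locus genotype, computed under
#' Hardy-Weinberg equilibrium as a product over loci of \code{2pq} for
#' heterozygotes and \code{p^2} for homozygotes.
#'
#' @param a,b \linkS4class{SampleReport} objects carrying STR calls.
#' @param freqs allele frequency table: data.frame with columns
#'   \code{locus}, \code{allele}, \code{freq}
#'   (see \code{\link{readFrequencyTable}}).
#' @return an \linkS4class{IdentityResult}.
#' @export
matchSamples <- function(a, b, freqs) {
    shared <- intersect(names(a@strCalls), names(b@strCalls))
    shared <- shared[vapply(shared, function(nm)
        length(a@strCalls[[nm]]@alleles) > 0L &&
            length(b@strCalls[[nm]]@alleles) > 0L, logical(1))]
    if (!length(shared))
        stop("no shared loci with called genotypes")
    genoOf <- function(call) {
        al <- call@alleles
        if (length(al) == 1L) c(al, al) else sort(al)
    }
    match <- all(vapply(shared, function(nm)
        isTRUE(all.equal(genoOf(a@strCalls[[nm]]),
                         genoOf(b@strCalls[[nm]]))), logical(1)))
    prob <- 1
    for (nm in shared) {
        f <- freqs[freqs$locus == nm, , drop = FALSE]
        if (!nrow(f))
            stop("locus '", nm, "' missing from the frequency table")
        g <- genoOf(a@strCalls[[nm]])
        getFreq <- function(al) {
            hit <- abs(f$allele - al) < 1e-9
            if (!any(hit))
                stop("allele ", al, " at locus '", nm,
                     "' missing from the frequency table")
            f$freq[hit][1L]
        }
        p <- getFreq(g[1L])
        prob <- prob * if (abs(g[1L] - g[2L]) < 1e-9) p^2
                       else 2 * p * getFreq(g[2L])
    }
    new("IdentityResult", match = match, comparedLoci = length(shared),
        matchProbability = prob)
}
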