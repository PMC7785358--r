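#' @import methods
NULL

# ---- assay panel component classes -------------------------------------

#' Restriction enzyme
#'
#' A restriction endonuclease described by its IUPAC recognition pattern and
#' the cut offset on the top strand. The two bundled enzymes, SexAI
#' (A/CCWGGT) and BspHI (T/CATGA), both have palindromic recognition
#' sequences and cut one base into the pattern.
#'
#' @slot name enzyme name, e.g. \code{"SexAI"}.
#' @slot recognition recognition pattern in IUPAC nucleotide codes.
#' @slot cutOffset cut position in bp from the 5' end of the pattern on the
#'   top strand (\code{0 <= cutOffset <= nchar(recognition)}).
#' @exportClass Enzyme
setClass("Enzyme",
    representation(name = "character", recognition = "character",
                   cutOffset = "integer"),
    validity = function(object) {
        msg <- character()
        if (length(object@name) != 1L || !nzchar(object@name))
            msg <- c(msg, "enzyme name must be a single non-empty string")
        if (length(object@recognition) != 1L ||
            !grepl("^[ACGTRYSWKMBDHVN]+$", object@recognition))
            msg <- c(msg, sprintf(
                "enzyme '%s': recognition must contain only IUPAC codes ACGTRYSWKMBDHVN",
                object@name))
        else if (object@cutOffset < 0L ||
                 object@cutOffset > nchar(object@recognition))
            msg <- c(msg, sprintf(
                "enzyme '%s': cut_offset must lie within [0, pattern length]",
                object@name))
        if (length(msg)) msg else TRUE
    })

#' Construct an \linkS4class{Enzyme}
#' @param name enzyme name.
#' @param recognition IUPAC recognition pattern.
#' @param cutOffset integer cut offset from the pattern's 5' end.
#' @return an \code{Enzyme} object.
#' @examples
#' Enzyme("BspHI", "TCATGA", 1)
#' @export
Enzyme <- function(name, recognition, cutOffset) {
    new("Enzyme", name = as.character(name),
        recognition = toupper(as.character(recognition)),
        cutOffset = as.integer(cutOffset))
}

#' Fluorescently labeled primer pair
#'
#' One primer pair of the multiplex, optionally 5'-labeled with a dye on
#' either primer. Unlabeled fragments are invisible on the capillary, so at
#' least one primer of each pair must carry a dye.
#'
#' @slot amplicon name of the amplicon this pair produces (e.g.
#'   \code{"HFE_exon2"}).
#' @slot upperSeq,lowerSeq primer sequences, uppercase ACGT.
#' @slot upperDye,lowerDye dye name or \code{NA} for an unlabeled primer.
#' @exportClass PrimerPair
setClass("PrimerPair",
    representation(amplicon = "character", upperSeq = "character",
                   lowerSeq = "character", upperDye = "character",
                   lowerDye = "character"),
    validity = function(object) {
        msg <- character()
        for (s in c(object@upperSeq, object@lowerSeq))
            if (!grepl("^[ACGT]+$", s))
                msg <- c(msg, sprintf(
                    "primer pair '%s': sequences must be non-empty uppercase ACGT",
                    object@amplicon))
        if (is.na(object@upperDye) && is.na(object@lowerDye))
            msg <- c(msg, sprintf(
                "primer pair '%s': at least one primer must carry a dye (unlabeled fragments are invisible)",
                object@amplicon))
        if (length(msg)) unique(msg) else TRUE
    })

#' @rdname PrimerPair-class
#' @param amplicon,upperSeq,lowerSeq,upperDye,lowerDye see slots.
#' @return a \code{PrimerPair}.
#' @export
PrimerPair <- function(amplicon, upperSeq, lowerSeq,
                       upperDye = NA_character_, lowerDye = NA_character_) {
    new("PrimerPair", amplicon = amplicon, upperSeq = toupper(upperSeq),
        lowerSeq = toupper(lowerSeq),
        upperDye = as.character(upperDye), lowerDye = as.character(lowerDye))
}

#' RFLP marker
#'
#' A biallelic marker genotyped by presence/absence of a diagnostic
#' restriction site inside a labeled amplicon. When
#' \code{variantCreatesSite} is \code{TRUE}, the variant allele carries the
#' site and is read as the cut labeled fragment; the reference allele is
#' read as the uncut amplicon.
#'
#' @slot name marker name, e.g. \code{"C282Y"}.
#' @slot enzymeName name of the diagnostic enzyme.
#' @slot primerPair name of the amplicon/primer pair producing the marker.
#' @slot ampliconLength amplicon size in bp.
#' @slot sitePosition 0-based offset of the recognition-site start within
#'   the amplicon.
#' @slot variantCreatesSite does the variant allele create the site?
#' @slot labeledEnd \code{"five_prime"} or \code{"three_prime"}: which
#'   amplicon end carries the dye read for this marker.
#' @slot dye dye name.
#' @exportClass RFLPMarker
setClass("RFLPMarker",
    representation(name = "character", enzymeName = "character",
                   primerPair = "character", ampliconLength = "integer",
                   sitePosition = "integer", variantCreatesSite = "logical",
                   labeledEnd = "character", dye = "character"),
    validity = function(object) {
        msg <- character()
        if (object@sitePosition <= 0L ||
            object@sitePosition >= object@ampliconLength)
            msg <- c(msg, sprintf(
                "marker '%s': site_position must satisfy 0 < site < amplicon_length",
                object@name))
        if (!object@labeledEnd %in% c("five_prime", "three_prime"))
            msg <- c(msg, sprintf(
                "marker '%s': labeled_end must be 'five_prime' or 'three_prime'",
                object@name))
        if (length(msg)) msg else TRUE
    })

#' @rdname RFLPMarker-class
#' @param name,enzymeName,primerPair,ampliconLength,sitePosition,variantCreatesSite,labeledEnd,dye
#'   see slots.
#' @return an \code{RFLPMarker}.
#' @export
RFLPMarker <- function(name, enzymeName, primerPair, ampliconLength,
                       sitePosition, variantCreatesSite = TRUE,
                       labeledEnd = "five_prime", dye) {
    new("RFLPMarker", name = name, enzymeName = enzymeName,
        primerPair = primerPair, ampliconLength = as.integer(ampliconLength),
        sitePosition = as.integer(sitePosition),
        variantCreatesSite = isTRUE(variantCreatesSite),
        labeledEnd = labeledEnd, dye = dye)
}

#' Short tandem repeat locus
#'
#' An STR locus read on the fragment-size ladder
#' \code{size = sizeOffset + repeatUnitLength * repeats + microvariant bp}.
#' Allele designations use the forensic convention: integer repeat count
#' with partial repeats as a decimal (26.2 = 26 repeats + 2 bp).
#'
#' @slot name locus name (\code{"FGA"}, \code{"SE33"}).
#' @slot repeatUnitLength repeat unit in bp (4 for both bundled loci).
#' @slot sizeOffset fragment size in bp of a hypothetical 0-repeat allele
#'   (a constant of the fixture ladder).
#' @slot alleleMin,alleleMax allele designation range.
#' @slot stutterMean,stutterSD expected stutter ratio (fraction of parent
#'   allele height) and its standard deviation.
#' @slot dye dye name.
#' @exportClass STRLocus
setClass("STRLocus",
    representation(name = "character", repeatUnitLength = "integer",
                   sizeOffset = "numeric", alleleMin = "numeric",
                   alleleMax = "numeric", stutterMean = "numeric",
                   stutterSD = "numeric", dye = "character"),
    validity = function(object) {
        msg <- character()
        if (object@alleleMin >= object@alleleMax)
            msg <- c(msg, sprintf("locus '%s': allele_min must be < allele_max",
                                  object@name))
        if (object@stutterMean <= 0 || object@stutterMean >= 1)
            msg <- c(msg, sprintf("locus '%s': stutter_mean must be in (0, 1)",
                                  object@name))
        if (object@stutterSD <= 0)
            msg <- c(msg, sprintf("locus '%s': stutter_sd must be > 0",
                                  object@name))
        if (length(msg)) msg else TRUE
    })

#' @rdname STRLocus-class
#' @param name,repeatUnitLength,sizeOffset,alleleMin,alleleMax,stutterMean,stutterSD,dye
#'   see slots.
#' @return an \code{STRLocus}.
#' @export
STRLocus <- function(name, repeatUnitLength, sizeOffset, alleleMin, alleleMax,
                     stutterMean, stutterSD, dye) {
    new("STRLocus", name = name,
        repeatUnitLength = as.integer(repeatUnitLength),
        sizeOffset = as.numeric(sizeOffset), alleleMin = as.numeric(alleleMin),
        alleleMax = as.numeric(alleleMax), stutterMean = as.numeric(stutterMean),
        stutterSD = as.numeric(stutterSD), dye = dye)
}

#' Internal digestion-control fragment
#'
#' The co-amplified FZD1 fragment carries one obligate SexAI and one
#' obligate BspHI site, and both primers are labeled with the same dye, so
#' the two terminal double-digest fragments monitor both enzymes: an
#' undigested marker fragment can then be attributed to a missing site
#' rather than a failed digestion.
#'
#' @slot name fragment name (\code{"FZD1"}).
#' @slot ampliconLength amplicon size in bp.
#' @slot sexaiSiteStart,bsphiSiteStart 0-based recognition-site start
#'   positions within the amplicon.
#' @slot doubleDigestSizes named numeric, expected labeled sizes of the
#'   successful double digest per enzyme (114/147 bp in the default panel).
#' @slot singleFailureSizes named numeric, labeled size observed when the
#'   named enzyme fails while the other cuts.
#' @slot uncutSize size of the fully undigested amplicon.
#' @slot dye the dye carried by both primers.
#' @exportClass ControlFragment
setClass("ControlFragment",
    representation(name = "character", ampliconLength = "integer",
                   sexaiSiteStart = "integer", bsphiSiteStart = "integer",
                   doubleDigestSizes = "numeric", singleFailureSizes = "numeric",
                   uncutSize = "numeric", dye = "character"),
    validity = function(object) {
        msg <- character()
        sizes <- c(object@doubleDigestSizes, object@singleFailureSizes,
                   object@uncutSize)
        if (any(sizes > object@ampliconLength))
            msg <- c(msg, "control: all expected sizes must be <= amplicon_length")
        if (is.null(names(object@doubleDigestSizes)) ||
            is.null(names(object@singleFailureSizes)))
            msg <- c(msg, "control: double_digest_sizes and single_failure_sizes must be named by enzyme")
        if (length(object@dye) != 1L || is.na(object@dye))
            msg <- c(msg, "control: both primer ends must carry one (shared) dye")
        if (length(msg)) msg else TRUE
    })

#' @rdname ControlFragment-class
#' @param name,ampliconLength,sexaiSiteStart,bsphiSiteStart,doubleDigestSizes,singleFailureSizes,uncutSize,dye
#'   see slots.
#' @return a \code{ControlFragment}.
#' @export
ControlFragment <- function(name, ampliconLength, sexaiSiteStart,
                            bsphiSiteStart, doubleDigestSizes,
                            singleFailureSizes, uncutSize, dye) {
    new("ControlFragment", name = name,
        ampliconLength = as.integer(ampliconLength),
        sexaiSiteStart = as.integer(sexaiSiteStart),
        bsphiSiteStart = as.integer(bsphiSiteStart),
        doubleDigestSizes = stats::setNames(as.numeric(doubleDigestSizes),
                                            names(doubleDigestSizes)),
        singleFailureSizes = stats::setNames(as.numeric(singleFailureSizes),
                                             names(singleFailureSizes)),
        uncutSize = as.numeric(uncutSize), dye = dye)
}

#' Interpretation thresholds
#'
#' The analytical cutoff is always the product
#' \code{cutoffMultiplier * noiseCeiling} (250 RFU = 5 x 50 RFU in the
#' default panel); a stored inconsistent triple is rejected.
#'
#' @slot noiseCeiling maximum background peak height in RFU.
#' @slot cutoffMultiplier analytical-cutoff multiplier (dimensionless).
#' @slot analyticalCutoff peak-height cutoff in RFU.
#' @slot saturation detector saturation ceiling in RFU.
#' @slot stutterSDMultiplier the k of the mean + k*SD stutter
#'   contamination rule (2 in the default panel).
#' @exportClass Thresholds
setClass("Thresholds",
    representation(noiseCeiling = "numeric", cutoffMultiplier = "numeric",
                   analyticalCutoff = "numeric", saturation = "numeric",
                   stutterSDMultiplier = "numeric"),
    validity = function(object) {
        msg <- character()
        if (!isTRUE(all.equal(object@analyticalCutoff,
                              object@cutoffMultiplier * object@noiseCeiling)))
            msg <- c(msg, sprintf(
                "thresholds: analytical_cutoff (%g) must equal cutoff_multiplier x noise_ceiling (%g x %g)",
                object@analyticalCutoff, object@cutoffMultiplier,
                object@noiseCeiling))
        if (object@saturation <= object@analyticalCutoff)
            msg <- c(msg, "thresholds: saturation must exceed the analytical cutoff")
        if (length(msg)) msg else TRUE
    })

#' @rdname Thresholds-class
#' @param noiseCeiling,cutoffMultiplier,saturation,stutterSDMultiplier see
#'   slots.
#' @param analyticalCutoff optional; recomputed as
#'   \code{cutoffMultiplier * noiseCeiling} when missing, validated against
#'   that product when supplied.
#' @return a \code{Thresholds} object.
#' @export
Thresholds <- function(noiseCeiling, cutoffMultiplier,
                       analyticalCutoff = cutoffMultiplier * noiseCeiling,
                       saturation, stutterSDMultiplier = 2) {
    new("Thresholds", noiseCeiling = as.numeric(noiseCeiling),
        cutoffMultiplier = as.numeric(cutoffMultiplier),
        analyticalCutoff = as.numeric(analyticalCutoff),
        saturation = as.numeric(saturation),
        stutterSDMultiplier = as.numeric(stutterSDMultiplier))
}

#' Multiplex assay panel
#'
#' Full declarative description of the multiplex PCR-RFLP assay: enzymes,
#' labeled primer pairs, RFLP markers, STR loci, the internal digestion
#' control and the interpretation thresholds. Use \code{\link{loadPanel}} /
#' \code{\link{defaultPanel}} to obtain a fully validated panel.
#'
#' @slot schemaVersion config schema version.
#' @slot dyes the dye names legal in this panel.
#' @slot enzymes named list of \linkS4class{Enzyme}.
#' @slot primerPairs named list of \linkS4class{PrimerPair} (by amplicon).
#' @slot rflpMarkers named list of \linkS4class{RFLPMarker}.
#' @slot strLoci named list of \linkS4class{STRLocus}.
#' @slot control a \linkS4class{ControlFragment}.
#' @slot thresholds a \linkS4class{Thresholds}.
#' @exportClass AssayPanel
setClass("AssayPanel",
    representation(schemaVersion = "integer", dyes = "character",
                   enzymes = "list", primerPairs = "list",
                   rflpMarkers = "list", strLoci = "list",
                   control = "ControlFragment", thresholds = "Thresholds"),
    validity = function(object) {
        msg <- character()
        memberClass <- c(enzymes = "Enzyme", primerPairs = "PrimerPair",
                         rflpMarkers = "RFLPMarker", strLoci = "STRLocus")
        for (slotname in names(memberClass)) {
            items <- slot(object, slotname)
            if (!all(vapply(items, is, logical(1), memberClass[[slotname]])))
                msg <- c(msg, sprintf("slot '%s' must contain only %s objects",
                                      slotname, memberClass[[slotname]]))
        }
        enzNames <- vapply(object@enzymes, function(e) e@name, character(1))
        ppNames <- vapply(object@primerPairs, function(p) p@amplicon, character(1))
        for (m in object@rflpMarkers) {
            if (!m@enzymeName %in% enzNames)
                msg <- c(msg, sprintf(
                    "marker '%s' references enzyme '%s' not defined in the panel",
                    m@name, m@enzymeName))
            if (!m@primerPair %in% ppNames)
                msg <- c(msg, sprintf(
                    "marker '%s' references primer pair '%s' not defined in the panel",
                    m@name, m@primerPair))
        }
        if (!all(names(object@control@doubleDigestSizes) %in% enzNames))
            msg <- c(msg, "control double_digest_sizes must be named by panel enzymes")
        allDyes <- c(
            unlist(lapply(object@primerPairs,
                          function(p) c(p@upperDye, p@lowerDye))),
            vapply(object@rflpMarkers, function(m) m@dye, character(1)),
            vapply(object@strLoci, function(l) l@dye, character(1)),
            object@control@dye)
        bad <- setdiff(allDyes[!is.na(allDyes)], object@dyes)
        if (length(bad))
            msg <- c(msg, sprintf("dye(s) not in the panel dye list: %s",
                                  paste(unique(bad), collapse = ", ")))
        if (length(msg)) msg else TRUE
    })

# ---- sample-level classes ----------------------------------------------

#' Ground-truth sample genotype
#'
#' The generating truth handed to the simulator: per-marker RFLP allele
#' states, per-locus STR allele pairs, the (assay-silent) S65C status, an
#' optional whole-enzyme digestion failure, and the DNA input.
#'
#' @slot rflpAlleles named list; per marker an unordered pair of
#'   \code{"site_present"} / \code{"site_absent"}.
#' @slot strAlleles named list; per locus an unordered numeric pair of
#'   allele designations. May be empty, in which case
#'   \code{\link{simulateCohort}} draws alleles uniformly from the ladder.
#' @slot s65cStatus \code{"ref_hom"}, \code{"het"} or \code{"var_hom"}; has
#'   no effect on BspHI cleavage and therefore on any peak.
#' @slot digestionFailure \code{NA} or the name of an enzyme whose
#'   digestion completely failed in this reaction.
#' @slot dnaInput DNA input in ng per reaction.
#' @exportClass SampleGenotype
setClass("SampleGenotype",
    representation(rflpAlleles = "list", strAlleles = "list",
                   s65cStatus = "character", digestionFailure = "character",
                   dnaInput = "numeric"),
    validity = function(object) {
        msg <- character()
        for (nm in names(object@rflpAlleles)) {
            al <- object@rflpAlleles[[nm]]
            if (length(al) != 2L || !all(al %in% c("site_present", "site_absent")))
                msg <- c(msg, sprintf(
                    "rflp_alleles['%s'] must be a pair of 'site_present'/'site_absent'", nm))
        }
        for (nm in names(object@strAlleles)) {
            al <- object@strAlleles[[nm]]
            if (length(al) != 2L || !is.numeric(al))
                msg <- c(msg, sprintf(
                    "str_alleles['%s'] must be a numeric pair of designations", nm))
        }
        if (!object@s65cStatus %in% c("ref_hom", "het", "var_hom"))
            msg <- c(msg, "s65c_status must be 'ref_hom', 'het' or 'var_hom'")
        if (!(length(object@dnaInput) == 1L && object@dnaInput > 0))
            msg <- c(msg, "dna_input must be a single positive number (ng)")
        if (length(msg)) msg else TRUE
    })

#' Fluorescent peak table
#'
#' One sample's capillary-electrophoresis fragment-analysis output: peaks
#' as (dye, size in bp, height in RFU). Peaks are stored sorted by dye then
#' size, with at most one peak per (dye, 1-bp size bin); the constructor
#' merges co-binned peaks by summing their heights.
#'
#' @slot sampleID sample identifier.
#' @slot peaks \code{data.frame} with columns \code{dye}, \code{size},
#'   \code{height}.
#' @slot metadata free-form list (DNA input, seed, mixture description...).
#' @exportClass PeakTable
setClass("PeakTable",
    representation(sampleID = "character", peaks = "data.frame",
                   metadata = "list"),
    validity = function(object) {
        msg <- character()
        pk <- object@peaks
        if (!all(c("dye", "size", "height") %in% names(pk)))
            msg <- c(msg, "peaks must have columns dye, size, height")
        else {
            if (nrow(pk) && any(pk$height < 0))
                msg <- c(msg, "peak heights must be >= 0")
            if (nrow(pk) > 1L) {
                o <- order(pk$dye, pk$size)
                if (!identical(o, seq_len(nrow(pk))))
                    msg <- c(msg, "peaks must be sorted by dye then size")
                if (anyDuplicated(paste(pk$dye, round(pk$size))))
                    msg <- c(msg, "at most one peak per (dye, 1-bp size bin)")
            }
        }
        if (length(msg)) msg else TRUE
    })

#' @rdname PeakTable-class
#' @param sampleID sample identifier.
#' @param peaks data.frame with columns \code{dye}, \code{size},
#'   \code{height}; peaks falling in the same (dye, 1-bp) bin are merged by
#'   summing heights (size becomes the height-weighted mean).
#' @param metadata free-form list.
#' @return a \code{PeakTable}.
#' @export
PeakTable <- function(sampleID, peaks, metadata = list()) {
    stopifnot(is.data.frame(peaks),
              all(c("dye", "size", "height") %in% names(peaks)))
    pk <- peaks[, c("dye", "size", "height")]
    pk$dye <- as.character(pk$dye)
    if (nrow(pk)) {
        key <- paste(pk$dye, round(pk$size))
        if (anyDuplicated(key)) {
            h <- tapply(pk$height, key, sum)
            s <- tapply(pk$height * pk$size, key, sum) / h
            d <- tapply(pk$dye, key, `[`, 1L)
            pk <- data.frame(dye = as.character(d), size = as.numeric(s),
                             height = as.numeric(h))
        }
        pk <- pk[order(pk$dye, pk$size), , drop = FALSE]
        rownames(pk) <- NULL
    }
    new("PeakTable", sampleID = as.character(sampleID), peaks = pk,
        metadata = metadata)
}

# ---- call / report classes ---------------------------------------------

#' Digestion-control status
#'
#' @slot amplificationOK was any control-channel peak detected above the
#'   cutoff?
#' @slot enzymeStatus named character, per enzyme one of \code{"pass"},
#'   \code{"fail"}, \code{"indeterminate"}.
#' @slot evidence numeric vector of matched control peak sizes.
#' @exportClass ControlStatus
setClass("ControlStatus",
    representation(amplificationOK = "logical", enzymeStatus = "character",
                   evidence = "numeric"),
    validity = function(object) {
        msg <- character()
        if (!all(object@enzymeStatus %in% c("pass", "fail", "indeterminate")))
            msg <- c(msg, "enzyme status values must be pass/fail/indeterminate")
        if (!object@amplificationOK &&
            !all(object@enzymeStatus == "indeterminate"))
            msg <- c(msg, "without control amplification both enzymes must be indeterminate")
        if (length(msg)) msg else TRUE
    })

#' Per-marker RFLP genotype call
#'
#' @slot markerName marker name.
#' @slot genotype \code{"ref_hom"}, \code{"het"}, \code{"var_hom"} or
#'   \code{"no_call"}.
#' @slot supportingPeaks data.frame of the peaks supporting the call.
#' @slot reason controlled-vocabulary reason when \code{no_call}:
#'   \code{control_fail}, \code{amplification_fail}, \code{no_peaks} or
#'   \code{ambiguous}; \code{NA} otherwise.
#' @exportClass MarkerCall
setClass("MarkerCall",
    representation(markerName = "character", genotype = "character",
                   supportingPeaks = "data.frame", reason = "character"),
    validity = function(object) {
        if (!object@genotype %in% c("ref_hom", "het", "var_hom", "no_call"))
            return("genotype must be ref_hom/het/var_hom/no_call")
        if (object@genotype == "no_call" &&
            !object@reason %in% c("control_fail", "amplification_fail",
                                  "no_peaks", "ambiguous"))
            return("no_call must carry a controlled-vocabulary reason")
        TRUE
    })

#' Per-locus STR call
#'
#' @slot locusName locus name.
#' @slot alleles one (homozygote) or two allele designations.
#' @slot peakHeights heights in RFU, parallel to \code{alleles}.
#' @slot extraAlleles designations of surviving non-stutter peaks beyond
#'   the two tallest (contamination evidence).
#' @slot extraHeights heights parallel to \code{extraAlleles}.
#' @slot offLadder sizes in bp of peaks outside the locus allele range.
#' @exportClass STRCall
setClass("STRCall",
    representation(locusName = "character", alleles = "numeric",
                   peakHeights = "numeric", extraAlleles = "numeric",
                   extraHeights = "numeric", offLadder = "numeric"),
    validity = function(object) {
        if (length(object@alleles) > 2L)
            return("an STR call carries at most two allele designations")
        if (length(object@alleles) != length(object@peakHeights))
            return("peakHeights must parallel alleles")
        TRUE
    })

#' Contamination report
#'
#' @slot flagged \code{TRUE} iff any evidence was found.
#' @slot evidence data.frame with columns \code{kind} (one of
#'   \code{extra_str_allele}, \code{elevated_stutter},
#'   \code{extra_rflp_peak}), \code{locus}, \code{size}, \code{height},
#'   \code{detail}.
#' @exportClass ContaminationReport
setClass("ContaminationReport",
    representation(flagged = "logical", evidence = "data.frame"),
    validity = function(object) {
        if (!identical(object@flagged, nrow(object@evidence) > 0L))
            return("flagged must be TRUE iff evidence is nonempty")
        if (nrow(object@evidence) &&
            !all(object@evidence$kind %in%
                 c("extra_str_allele", "elevated_stutter", "extra_rflp_peak")))
            return("unknown evidence kind")
        TRUE
    })

#' Aggregated per-sample report
#'
#' @slot sampleID sample identifier.
#' @slot control a \linkS4class{ControlStatus}.
#' @slot markerCalls named list of \linkS4class{MarkerCall}, one per panel
#'   marker.
#' @slot strCalls named list of \linkS4class{STRCall}, one per panel locus.
#' @slot contamination \code{NULL} or a \linkS4class{ContaminationReport}.
#' @exportClass SampleReport
setClass("SampleReport",
    representation(sampleID = "character", control = "ControlStatus",
                   markerCalls = "list", strCalls = "list",
                   contamination = "ANY"))

#' STR identity comparison result
#'
#' @slot match \code{TRUE} iff all shared-locus genotypes are equal.
#' @slot comparedLoci number of loci compared.
#' @slot matchProbability probability of a random multi-locus genotype
#'   coincidence under Hardy-Weinberg equilibrium.
#' @exportClass IdentityResult
setClass("IdentityResult",
    representation(match = "logical", comparedLoci = "integer",
                   matchProbability = "numeric"),
    validity = function(object) {
        if (object@matchProbability <= 0 || object@matchProbability > 1)
            return("match probability must lie in (0, 1]")
        TRUE
    })

#' Synthetic template amplicon
#'
#' A concrete DNA realization of one marker allele, beginning with the
#' upper primer and ending with the reverse complement of the lower primer.
#'
#' @slot markerName marker this amplicon realizes.
#' @slot sequence uppercase ACGT amplicon sequence.
#' @slot dye5,dye3 dye on the 5'/3' terminal fragment, \code{NA} if that
#'   end is unlabeled.
#' @exportClass Amplicon
setClass("Amplicon",
    representation(markerName = "character", sequence = "character",
                   dye5 = "character", dye3 = "character"),
    validity = function(object) {
        if (!grepl("^[ACGT]+$", object@sequence))
            return("amplicon sequence must be uppercase ACGT")
        TRUE
    })
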