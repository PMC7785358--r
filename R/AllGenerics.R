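# Generics and accessors. Slot access from user code should go through
# these rather than @.

#' @name accessors
#' @title Accessors for hfeRFLP objects
#' @description Extract components of panels, peak tables and reports.
#' @param object an hfeRFLP object.
#' @return the requested component.
#' @examples
#' panel <- defaultPanel()
#' analyticalCutoff(panel)
#' names(rflpMarkers(panel))
NULL

#' @rdname accessors
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))
#' @rdname accessors
#' @export
setGeneric("sampleID", function(object) standardGeneric("sampleID"))
#' @rdname accessors
#' @export
setGeneric("thresholds", function(object) standardGeneric("thresholds"))
#' @rdname accessors
#' @export
setGeneric("analyticalCutoff", function(object) standardGeneric("analyticalCutoff"))
#' @rdname accessors
#' @export
setGeneric("saturationLimit", function(object) standardGeneric("saturationLimit"))
#' @rdname accessors
#' @export
setGeneric("enzymes", function(object) standardGeneric("enzymes"))
#' @rdname accessors
#' @export
setGeneric("primerPairs", function(object) standardGeneric("primerPairs"))
#' @rdname accessors
#' @export
setGeneric("rflpMarkers", function(object) standardGeneric("rflpMarkers"))
#' @rdname accessors
#' @export
setGeneric("strLoci", function(object) standardGeneric("strLoci"))
#' @rdname accessors
#' @export
setGeneric("controlFragment", function(object) standardGeneric("controlFragment"))
#' @rdname accessors
#' @export
setGeneric("markerCalls", function(object) standardGeneric("markerCalls"))
#' @rdname accessors
#' @export
setGeneric("strCalls", function(object) standardGeneric("strCalls"))
#' @rdname accessors
#' @export
setGeneric("controlStatus", function(object) standardGeneric("controlStatus"))
#' @rdname accessors
#' @export
setGeneric("contamination", function(object) standardGeneric("contamination"))
#' @rdname accessors
#' @export
setGeneric("isFlagged", function(object) standardGeneric("isFlagged"))
#' @rdname accessors
#' @export
setGeneric("evidence", function(object) standardGeneric("evidence"))

#' @rdname accessors
#' @export
setMethod("peaks", "PeakTable", function(object) object@peaks)
#' @rdname accessors
#' @export
setMethod("sampleID", "PeakTable", function(object) object@sampleID)
#' @rdname accessors
#' @export
setMethod("sampleID", "SampleReport", function(object) object@sampleID)
#' @rdname accessors
#' @export
setMethod("thresholds", "AssayPanel", function(object) object@thresholds)
#' @rdname accessors
#' @export
setMethod("analyticalCutoff", "AssayPanel",
          function(object) object@thresholds@analyticalCutoff)
#' @rdname accessors
#' @export
setMethod("analyticalCutoff", "Thresholds",
          function(object) object@analyticalCutoff)
#' @rdname accessors
#' @export
setMethod("saturationLimit", "AssayPanel",
          function(object) object@thresholds@saturation)
#' @rdname accessors
#' @export
setMethod("enzymes", "AssayPanel", function(object) object@enzymes)
#' @rdname accessors
#' @export
setMethod("primerPairs", "AssayPanel", function(object) object@primerPairs)
#' @rdname accessors
#' @export
setMethod("rflpMarkers", "AssayPanel", function(object) object@rflpMarkers)
#' @rdname accessors
#' @export
setMethod("strLoci", "AssayPanel", function(object) object@strLoci)
#' @rdname accessors
#' @export
setMethod("controlFragment", "AssayPanel", function(object) object@control)
#' @rdname accessors
#' @export
setMethod("markerCalls", "SampleReport", function(object) object@markerCalls)
#' @rdname accessors
#' @export
setMethod("strCalls", "SampleReport", function(object) object@strCalls)
#' @rdname accessors
#' @export
setMethod("controlStatus", "SampleReport", function(object) object@control)
#' @rdname accessors
#' @export
setMethod("contamination", "SampleReport", function(object) object@contamination)
#' @rdname accessors
#' @export
setMethod("isFlagged", "ContaminationReport", function(object) object@flagged)
#' @rdname accessors
#' @export
setMethod("evidence", "ContaminationReport", function(object) object@evidence)

# ---- show methods ------------------------------------------------------

setMethod("show", "AssayPanel", function(object) {
    cat("AssayPanel (schema v", object@schemaVersion, ")\n", sep = "")
    cat("  enzymes:     ", paste(vapply(object@enzymes, slot, character(1),
                                        "name"), collapse = ", "), "\n")
    cat("  RFLP markers:", paste(names(object@rflpMarkers), collapse = ", "),
        "\n")
    cat("  STR loci:    ", paste(names(object@strLoci), collapse = ", "), "\n")
    cat("  control:     ", object@control@name, "(",
        paste(object@control@doubleDigestSizes, collapse = "/"),
        "bp double digest )\n")
    cat("  cutoff:", object@thresholds@analyticalCutoff, "RFU; saturation:",
        object@thresholds@saturation, "RFU\n")
})

setMethod("show", "PeakTable", function(object) {
    cat("PeakTable '", object@sampleID, "': ", nrow(object@peaks),
        " peaks\n", sep = "")
    if (nrow(object@peaks)) {
        tab <- table(object@peaks$dye)
        for (d in names(tab)) {
            sel <- object@peaks$dye == d
            cat(sprintf("  %-14s %2d peaks, max %.0f RFU\n", d, tab[[d]],
                        max(object@peaks$height[sel])))
        }
    }
})

setMethod("show", "SampleReport", function(object) {
    cat("SampleReport '", object@sampleID, "'\n", sep = "")
    st <- object@control
    cat("  control: amplification", if (st@amplificationOK) "ok" else "FAILED",
        "|", paste(names(st@enzymeStatus), st@enzymeStatus, collapse = ", "),
        "\n")
    for (mc in object@markerCalls)
        cat(sprintf("  %-6s %s%s\n", mc@markerName, mc@genotype,
                    if (mc@genotype == "no_call")
                        paste0(" (", mc@reason, ")") else ""))
    for (sc in object@strCalls)
        cat(sprintf("  %-6s %s%s\n", sc@locusName,
                    paste(sc@alleles, collapse = "/"),
                    if (length(sc@extraAlleles))
                        paste0(" + extra: ",
                               paste(sc@extraAlleles, collapse = "/")) else ""))
    if (is(object@contamination, "ContaminationReport"))
        cat("  contamination:",
            if (object@contamination@flagged) "FLAGGED" else "clean", "\n")
})

setMethod("show", "ContaminationReport", function(object) {
    if (!object@flagged) {
        cat("ContaminationReport: clean\n")
    } else {
        cat("ContaminationReport: FLAGGED,", nrow(object@evidence),
            "finding(s)\n")
        print(object@evidence)
    }
})
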