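# Sequence-level engine: IUPAC-aware restriction-site scanning, in-silico
# digestion, peak-size prediction and synthetic template construction.
#
# Coordinates are 0-based, half-open throughout; a cut position k splits a
# sequence into [0, k) and [k, length).

# All recognition-site windows of `enzyme` on `sequence`, both strands.
# Returns data.frame(start, end, orientation) in 0-based half-open
# coordinates; a window matching in both orientations (always the case for
# palindromic patterns) is reported once, as "forward".
.siteWindows <- function(sequence, enzyme) {
    subject <- Biostrings::DNAString(sequence)
    fwd <- Biostrings::matchPattern(enzyme@recognition, subject,
                                    fixed = FALSE)
    rcpat <- .revComp(enzyme@recognition)
    rev <- Biostrings::matchPattern(rcpat, subject, fixed = FALSE)
    f <- data.frame(start = Biostrings::start(fwd) - 1L,
                    end = Biostrings::end(fwd),
                    orientation = rep("forward", length(fwd)))
    r <- data.frame(start = Biostrings::start(rev) - 1L,
                    end = Biostrings::end(rev),
                    orientation = rep("reverse", length(rev)))
    r <- r[!r$start %in% f$start, , drop = FALSE]
    out <- rbind(f, r)
    out[order(out$start), , drop = FALSE]
}

#' Find restriction cut positions on a sequence
#'
#' Scans both strands for the enzyme's IUPAC recognition pattern
#' (\code{W} matches A or T, etc.) and returns top-strand cut coordinates,
#' 0-based, sorted and deduplicated. For a forward-orientation site
#' starting at \code{s} the cut is \code{s + cutOffset}; for a site found
#' only in reverse orientation the cut is \code{end - cutOffset}. For the
#' bundled palindromic enzymes the reverse scan adds nothing.
#'
#' @param sequence uppercase ACGT string.
#' @param enzyme an \linkS4class{Enzyme}.
#' @return integer vector of cut positions (bp from the 5' end, 0-based).
#' @examples
#' bsphi <- Enzyme("BspHI", "TCATGA", 1)
#' findSites("GGTCATGAGG", bsphi)  # 3
#' @export
findSites <- function(sequence, enzyme) {
    .assertDNA(sequence)
    stopifnot(is(enzyme, "Enzyme"))
    w <- .siteWindows(sequence, enzyme)
    if (!nrow(w)) return(integer())
    cuts <- ifelse(w$orientation == "forward",
                   w$start + enzyme@cutOffset,
                   w$end - enzyme@cutOffset)
    sort(unique(as.integer(cuts)))
}

#' Construct an \linkS4class{Amplicon}
#' @param markerName marker the amplicon realizes.
#' @param sequence uppercase ACGT sequence.
#' @param dye5,dye3 dye carried by the 5'/3' labeled end (\code{NA} if
#'   unlabeled).
#' @return an \code{Amplicon}.
#' @export
Amplicon <- function(markerName, sequence, dye5 = NA_character_,
                     dye3 = NA_character_) {
    new("Amplicon", markerName = markerName, sequence = toupper(sequence),
        dye5 = as.character(dye5), dye3 = as.character(dye3))
}

#' Digest an amplicon in silico
#'
#' Applies all cuts of all enzymes simultaneously (complete digestion) and
#' returns the resulting fragments left to right. Fragment lengths always
#' sum to the amplicon length. Only terminal fragments can retain a label:
#' the first fragment carries the 5' dye, the last the 3' dye (an uncut
#' amplicon is one fragment carrying both).
#'
#' @param amplicon an \linkS4class{Amplicon}.
#' @param enzymes list of \linkS4class{Enzyme} objects (possibly empty).
#' @return data.frame with columns \code{start}, \code{end}, \code{length},
#'   \code{dye5}, \code{dye3}, \code{dye} (the label visible on this
#'   fragment, \code{NA} if dark), \code{cutBy} (enzymes bounding the
#'   fragment, comma-separated).
#' @examples
#' panel <- defaultPanel()
#' tpl <- buildFixtureTemplates(panel, seed = 1)
#' frg <- digestAmplicon(tpl$FZD1$control, enzymes(panel))
#' frg$length  # 114 48 147
#' @export
digestAmplicon <- function(amplicon, enzymes) {
    stopifnot(is(amplicon, "Amplicon"))
    len <- nchar(amplicon@sequence)
    cutList <- lapply(enzymes, function(e) findSites(amplicon@sequence, e))
    names(cutList) <- vapply(enzymes, slot, character(1), "name")
    cuts <- sort(unique(unlist(cutList)))
    cuts <- cuts[cuts > 0L & cuts < len]
    bounds <- c(0L, cuts, len)
    n <- length(bounds) - 1L
    enzymeAt <- function(pos) {
        hit <- names(cutList)[vapply(cutList, function(x) pos %in% x,
                                     logical(1))]
        if (length(hit)) paste(hit, collapse = "+") else NA_character_
    }
    leftEnz <- vapply(bounds[-length(bounds)], enzymeAt, character(1))
    rightEnz <- vapply(bounds[-1L], enzymeAt, character(1))
    out <- data.frame(
        start = bounds[-length(bounds)], end = bounds[-1L],
        length = diff(bounds),
        dye5 = c(amplicon@dye5, rep(NA_character_, n - 1L)),
        dye3 = c(rep(NA_character_, n - 1L), amplicon@dye3))
    out$dye <- ifelse(!is.na(out$dye5), out$dye5, out$dye3)
    out$cutBy <- ifelse(
        is.na(leftEnz) & is.na(rightEnz), NA_character_,
        paste(ifelse(is.na(leftEnz), "", leftEnz),
              ifelse(is.na(rightEnz), "", rightEnz), sep = "|"))
    out
}

#' Predict the expected peak-size set for a genotype
#'
#' Ideal (noise-free) sizes per dye channel: for each RFLP marker the
#' labeled cut-fragment size if a site-bearing allele is present and the
#' uncut amplicon size if a site-free allele is present (both for
#' heterozygotes); one size per distinct STR allele; and the control's
#' double-digest sizes, always.
#'
#' @param panel an \linkS4class{AssayPanel}.
#' @param genotype a \linkS4class{SampleGenotype} (see
#'   \code{\link{makeGenotype}}).
#' @return data.frame with columns \code{dye}, \code{size}, \code{origin}.
#' @export
predictPeakSizes <- function(panel, genotype) {
    stopifnot(is(genotype, "SampleGenotype"))
    out <- list()
    for (m in panel@rflpMarkers) {
        al <- genotype@rflpAlleles[[m@name]]
        if (is.null(al)) next
        states <- unique(al)
        sz <- vapply(states, function(s)
            if (s == "site_present") .markerCutSize(panel, m)
            else .markerUncutSize(m), numeric(1))
        out[[length(out) + 1L]] <- data.frame(
            dye = m@dye, size = unname(sz),
            origin = paste0(m@name, ":", states))
    }
    for (l in panel@strLoci) {
        al <- genotype@strAlleles[[l@name]]
        if (is.null(al)) next
        if (any(al < l@alleleMin - 1e-9 | al > l@alleleMax + 1e-9))
            stop("STR allele outside the ", l@name, " range [",
                 l@alleleMin, ", ", l@alleleMax, "]")
        des <- unique(al)
        out[[length(out) + 1L]] <- data.frame(
            dye = l@dye, size = .strSize(l, des),
            origin = paste0(l@name, ":", format(des, trim = TRUE)))
    }
    ctl <- panel@control
    out[[length(out) + 1L]] <- data.frame(
        dye = ctl@dye, size = unname(ctl@doubleDigestSizes),
        origin = paste0(ctl@name, ":", names(ctl@doubleDigestSizes),
                        "_digest"))
    res <- do.call(rbind, out)
    res <- res[order(res$dye, res$size), , drop = FALSE]
    rownames(res) <- NULL
    res
}

# ---- synthetic template construction -----------------------------------

# concrete instantiation of an IUPAC pattern (first compatible base per
# position; SexAI's W becomes A) and a single-base disruption of it
.concreteSite <- function(recognition) {
    paste(vapply(strsplit(recognition, "")[[1]],
                 function(ch) .iupacBases(ch)[1L], character(1)),
          collapse = "")
}

.disruptSite <- function(recognition) {
    chars <- strsplit(.concreteSite(recognition), "")[[1]]
    pat <- strsplit(recognition, "")[[1]]
    # change the base after the first position whose pattern character is
    # not N; pick a base incompatible with the pattern there
    for (i in seq_along(pat)) {
        allowed <- .iupacBases(pat[i])
        forbidden <- setdiff(c("A", "C", "G", "T"), allowed)
        if (length(forbidden)) {
            chars[i] <- forbidden[1L]
            return(paste(chars, collapse = ""))
        }
    }
    stop("recognition pattern cannot be disrupted (all-N)")
}

.stamp <- function(seqChars, at0, piece) {
    idx <- at0 + seq_len(nchar(piece))
    seqChars[idx] <- strsplit(piece, "")[[1]]
    seqChars
}

# remove every enzyme site outside the protected windows by deterministic
# single-base edits in mutable (non-primer, non-protected) positions
.scrubOffTarget <- function(seqChars, enzymes, protected, immutable,
                            maxIter = 200L) {
    seqStr <- paste(seqChars, collapse = "")
    for (iter in seq_len(maxIter)) {
        windows <- do.call(rbind, lapply(enzymes, function(e) {
            w <- .siteWindows(seqStr, e)
            if (nrow(w)) cbind(w, enzyme = e@name) else NULL
        }))
        if (is.null(windows) || !nrow(windows)) return(seqChars)
        keep <- rep(TRUE, nrow(windows))
        for (p in protected)
            keep <- keep & !(windows$start == p$start &
                             windows$enzyme == p$enzyme)
        windows <- windows[keep, , drop = FALSE]
        if (!nrow(windows)) return(seqChars)
        w <- windows[1L, ]
        enz <- NULL
        for (e in enzymes) if (e@name == w$enzyme) enz <- e
        pat <- strsplit(if (w$orientation == "forward") enz@recognition
                        else .revComp(enz@recognition), "")[[1]]
        fixed <- FALSE
        for (k in seq_along(pat)) {
            pos0 <- w$start + k - 1L
            if ((pos0 + 1L) %in% immutable) next
            forbidden <- setdiff(c("A", "C", "G", "T"), .iupacBases(pat[k]))
            if (!length(forbidden)) next
            seqChars[pos0 + 1L] <- forbidden[1L]
            fixed <- TRUE
            break
        }
        if (!fixed)
            stop("unsatisfiable template layout: off-target site at ",
                 w$start, " overlaps an immutable region")
        seqStr <- paste(seqChars, collapse = "")
    }
    stop("template scrubbing did not converge")
}

#' Build synthetic template amplicons for the panel
#'
#' Constructs, deterministically for a given seed, one concrete DNA
#' amplicon per marker allele: each begins with the upper primer and ends
#' with the reverse complement of the lower primer; the diagnostic
#' recognition site is present exactly once at the configured position on
#' the site-bearing allele and disrupted by a single base on the site-free
#' allele; no off-target SexAI/BspHI site survives anywhere. The exon-2
#' (H63D) amplicon carries a mutable position standing for the S65C SNP,
#' strictly outside the BspHI hexamer, realized in the extra allele
#' \code{site_absent_s65c}; the FZD1 control carries exactly one SexAI and
#' one BspHI site at their configured positions.
#'
#' Two different seeds give different filler sequence but identical
#' fragment-size predictions.
#'
#' @param panel an \linkS4class{AssayPanel}.
#' @param seed integer seed for the filler sequence.
#' @return nested list: \code{marker -> allele -> Amplicon}. RFLP markers
#'   expose \code{site_present} and \code{site_absent} (H63D additionally
#'   \code{site_absent_s65c}); the control exposes \code{control}.
#' @export
buildFixtureTemplates <- function(panel, seed) {
    set.seed(as.integer(seed))
    enzAll <- panel@enzymes
    res <- list()

    makeBase <- function(name, len, pp) {
        filler <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        filler <- .stamp(filler, 0L, pp@upperSeq)
        lower <- .revComp(pp@lowerSeq)
        .stamp(filler, len - nchar(lower), lower)
    }
    immutableFor <- function(len, pp, extra = integer()) {
        lowerLen <- nchar(pp@lowerSeq)
        c(seq_len(nchar(pp@upperSeq)),
          (len - lowerLen + 1L):len, extra)
    }

    for (m in panel@rflpMarkers) {
        pp <- panel@primerPairs[[m@primerPair]]
        enz <- enzAll[[m@enzymeName]]
        len <- m@ampliconLength
        site <- .concreteSite(enz@recognition)
        siteLen <- nchar(site)
        if (m@sitePosition < nchar(pp@upperSeq) ||
            m@sitePosition + siteLen > len - nchar(pp@lowerSeq))
            stop("unsatisfiable layout: diagnostic site of '", m@name,
                 "' overlaps a primer")
        base <- makeBase(m@name, len, pp)
        siteIdx <- m@sitePosition + seq_len(siteLen)
        s65cIdx <- integer()
        if (m@enzymeName == "BspHI") {
            # S65C stand-in: first filler position at least 10 bp past the
            # recognition hexamer
            s65cIdx <- m@sitePosition + siteLen + 10L + 1L
        }
        immut <- immutableFor(len, pp, c(siteIdx, s65cIdx))

        present <- .stamp(base, m@sitePosition, site)
        present <- .scrubOffTarget(present, enzAll,
                                   protected = list(list(
                                       start = m@sitePosition,
                                       enzyme = m@enzymeName)),
                                   immutable = immut)
        absent <- .stamp(present, m@sitePosition,
                         .disruptSite(enz@recognition))
        absent <- .scrubOffTarget(absent, enzAll, protected = list(),
                                  immutable = immut)
        alleles <- list(
            site_present = Amplicon(m@name, paste(present, collapse = ""),
                                    dye5 = if (m@labeledEnd == "five_prime")
                                        m@dye else NA_character_,
                                    dye3 = if (m@labeledEnd == "three_prime")
                                        m@dye else NA_character_),
            site_absent = Amplicon(m@name, paste(absent, collapse = ""),
                                   dye5 = if (m@labeledEnd == "five_prime")
                                       m@dye else NA_character_,
                                   dye3 = if (m@labeledEnd == "three_prime")
                                       m@dye else NA_character_))
        if (length(s65cIdx)) {
            var <- absent
            cur <- var[s65cIdx]
            alt <- setdiff(c("A", "C", "G", "T"), cur)[1L]
            var[s65cIdx] <- alt
            var <- .scrubOffTarget(var, enzAll, protected = list(),
                                   immutable = immut)
            alleles$site_absent_s65c <-
                Amplicon(m@name, paste(var, collapse = ""),
                         dye5 = alleles$site_absent@dye5,
                         dye3 = alleles$site_absent@dye3)
            attr(alleles, "s65c_position") <- s65cIdx - 1L
        }
        res[[m@name]] <- alleles
    }

    ctl <- panel@control
    pp <- panel@primerPairs[[ctl@name]]
    sexai <- enzAll[["SexAI"]]
    bsphi <- enzAll[["BspHI"]]
    base <- makeBase(ctl@name, ctl@ampliconLength, pp)
    sIdx <- ctl@sexaiSiteStart + seq_len(nchar(sexai@recognition))
    bIdx <- ctl@bsphiSiteStart + seq_len(nchar(bsphi@recognition))
    base <- .stamp(base, ctl@sexaiSiteStart, .concreteSite(sexai@recognition))
    base <- .stamp(base, ctl@bsphiSiteStart, .concreteSite(bsphi@recognition))
    base <- .scrubOffTarget(
        base, enzAll,
        protected = list(list(start = ctl@sexaiSiteStart, enzyme = "SexAI"),
                         list(start = ctl@bsphiSiteStart, enzyme = "BspHI")),
        immutable = immutableFor(ctl@ampliconLength, pp, c(sIdx, bIdx)))
    res[[ctl@name]] <- list(
        control = Amplicon(ctl@name, paste(base, collapse = ""),
                           dye5 = ctl@dye, dye3 = ctl@dye))
    res
}

#' Export fixture templates as FASTA
#'
#' One record per marker-allele, named \code{marker|allele}, suitable for
#' inspection or for external in-silico PCR tools.
#'
#' @param templates result of \code{\link{buildFixtureTemplates}}.
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
exportTemplates <- function(templates, path) {
    seqs <- character()
    for (marker in names(templates))
        for (allele in names(templates[[marker]]))
            seqs[paste0(marker, "|", allele)] <-
                templates[[marker]][[allele]]@sequence
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
    invisible(path)
}
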