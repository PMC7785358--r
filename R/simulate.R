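# Synthetic capillary-electrophoresis peak tables: signal model with
# noise floor, analytical threshold, saturation, DNA-input response,
# stutter, and two-person mixtures.
#
# Height model: a true-allele peak has expected height
#   H = hRef * (dna_ng / refInput) * efficiency * allele_share
# with lognormal multiplicative noise (sdlog = sdLog). The control (FZD1)
# amplifies with relative efficiency 0.2, which reproduces the assay's
# observed behavior: control digest peaks visible but below the 250 RFU
# cutoff at 2 ng input, and all true peaks within [250, 32000] RFU from
# 10 ng up (heights clip at the 32000 RFU saturation ceiling).

.SIGNAL <- list(hRef = 8000, refInput = 25, sdLog = 0.15,
                controlEfficiency = 0.2, noiseRate = 8,
                noiseSizeRange = c(60, 400), sizeJitter = 0.3)

#' Construct a ground-truth sample genotype
#'
#' @param c282y,h63d RFLP genotypes as \code{"ref_hom"}, \code{"het"} or
#'   \code{"var_hom"} (translated to site allele pairs through the panel's
#'   \code{variantCreatesSite} polarity).
#' @param fga,se33 numeric pair of STR allele designations, or \code{NULL}
#'   to let \code{\link{simulateCohort}} draw them uniformly from the
#'   ladder.
#' @param s65c S65C status (\code{"ref_hom"}, \code{"het"},
#'   \code{"var_hom"}); silent in this assay.
#' @param digestionFailure \code{NA} or an enzyme name whose digestion
#'   failed completely in this reaction.
#' @param dnaInput DNA input in ng (default 25, the mid-range of the
#'   15-50 ng working window).
#' @param panel panel used to translate RFLP genotypes into allele states.
#' @return a \linkS4class{SampleGenotype}.
#' @examples
#' g <- makeGenotype(c282y = "var_hom", h63d = "het",
#'                   fga = c(20, 24), se33 = c(17, 29))
#' @export
makeGenotype <- function(c282y = "ref_hom", h63d = "ref_hom", fga = NULL,
                         se33 = NULL, s65c = "ref_hom",
                         digestionFailure = NA_character_, dnaInput = 25,
                         panel = defaultPanel()) {
    toStates <- function(marker, g) {
        v <- if (marker@variantCreatesSite) "site_present" else "site_absent"
        r <- setdiff(c("site_present", "site_absent"), v)
        switch(g,
               ref_hom = c(r, r), het = c(r, v), var_hom = c(v, v),
               stop("RFLP genotype must be ref_hom/het/var_hom, got '", g, "'"))
    }
    rflp <- list()
    if ("C282Y" %in% names(panel@rflpMarkers))
        rflp$C282Y <- toStates(panel@rflpMarkers$C282Y, c282y)
    if ("H63D" %in% names(panel@rflpMarkers))
        rflp$H63D <- toStates(panel@rflpMarkers$H63D, h63d)
    str <- list()
    if (!is.null(fga)) str$FGA <- as.numeric(fga)
    if (!is.null(se33)) str$SE33 <- as.numeric(se33)
    new("SampleGenotype", rflpAlleles = rflp, strAlleles = str,
        s65cStatus = s65c, digestionFailure = as.character(digestionFailure),
        dnaInput = as.numeric(dnaInput))
}

# Expected (pre-noise) signal rows for one contributor at effective DNA
# input effDna: data.frame(dye, size, base, kind, locus, designation).
.expectedSignalRows <- function(panel, genotype, effDna, signal = .SIGNAL) {
    scale <- signal$hRef * effDna / signal$refInput
    rows <- list()
    add <- function(dye, size, base, kind, locus = NA_character_,
                    designation = NA_real_) {
        rows[[length(rows) + 1L]] <<- data.frame(
            dye = dye, size = size, base = base, kind = kind,
            locus = locus, designation = designation)
    }
    failure <- genotype@digestionFailure
    failed <- function(enzName) !is.na(failure) && failure == enzName

    ctl <- panel@control
    ctlBase <- scale * signal$controlEfficiency
    for (enzName in names(ctl@doubleDigestSizes)) {
        size <- if (failed(enzName)) ctl@singleFailureSizes[[enzName]]
                else ctl@doubleDigestSizes[[enzName]]
        add(ctl@dye, size, ctlBase, "control")
    }
    for (m in panel@rflpMarkers) {
        al <- genotype@rflpAlleles[[m@name]]
        if (is.null(al)) next
        if (failed(m@enzymeName)) {
            add(m@dye, .markerUncutSize(m), scale, "rflp")
        } else {
            tab <- table(al)
            for (state in names(tab)) {
                size <- if (state == "site_present") .markerCutSize(panel, m)
                        else .markerUncutSize(m)
                add(m@dye, size, scale * tab[[state]] / 2, "rflp")
            }
        }
    }
    for (l in panel@strLoci) {
        al <- genotype@strAlleles[[l@name]]
        if (is.null(al)) next
        if (any(al < l@alleleMin - 1e-9 | al > l@alleleMax + 1e-9))
            stop("STR allele outside the ", l@name, " range")
        tab <- table(al)
        for (d in names(tab)) {
            des <- as.numeric(d)
            add(l@dye, .strSize(l, des), scale * tab[[d]] / 2, "str_allele",
                locus = l@name, designation = des)
        }
    }
    do.call(rbind, rows)
}

# Render expected rows into a PeakTable: lognormal height noise, stutter
# one repeat unit short of every STR allele peak, bin merging, size
# jitter, baseline noise, saturation clipping. Consumes RNG; callers seed.
.renderPeakTable <- function(panel, rows, sampleID, metadata,
                             signal = .SIGNAL) {
    th <- panel@thresholds
    if (!is.null(rows) && nrow(rows)) {
        rows$height <- rows$base *
            stats::rlnorm(nrow(rows), meanlog = 0, sdlog = signal$sdLog)
        str <- rows[rows$kind == "str_allele", , drop = FALSE]
        if (nrow(str)) {
            unit <- vapply(str$locus, function(nm)
                panel@strLoci[[nm]]@repeatUnitLength, numeric(1))
            mu <- vapply(str$locus, function(nm)
                panel@strLoci[[nm]]@stutterMean, numeric(1))
            sdv <- vapply(str$locus, function(nm)
                panel@strLoci[[nm]]@stutterSD, numeric(1))
            ratio <- pmax(0, stats::rnorm(nrow(str), mu, sdv))
            stut <- data.frame(dye = str$dye, size = str$size - unit,
                               height = ratio * str$height)
            rows <- rbind(rows[, c("dye", "size", "height")], stut)
        } else {
            rows <- rows[, c("dye", "size", "height")]
        }
        # merge shared (dye, size) contributions before jitter
        key <- paste(rows$dye, rows$size)
        h <- tapply(rows$height, key, sum)
        d <- tapply(rows$dye, key, `[`, 1L)
        s <- tapply(rows$size, key, `[`, 1L)
        rows <- data.frame(dye = as.character(d), size = as.numeric(s),
                           height = as.numeric(h))
        rows$size <- rows$size +
            stats::runif(nrow(rows), -signal$sizeJitter, signal$sizeJitter)
    } else {
        rows <- data.frame(dye = character(), size = numeric(),
                           height = numeric())
    }
    noise <- do.call(rbind, lapply(panel@dyes, function(d) {
        k <- stats::rpois(1L, signal$noiseRate)
        if (!k) return(NULL)
        data.frame(dye = d,
                   size = stats::runif(k, signal$noiseSizeRange[1],
                                       signal$noiseSizeRange[2]),
                   height = stats::runif(k, 0, th@noiseCeiling))
    }))
    if (!is.null(noise) && nrow(noise)) {
        # background fluctuations sharing a size bin present as one peak
        # at their maximum, so blanks never exceed the noise ceiling
        key <- paste(noise$dye, round(noise$size))
        keep <- !duplicated(key)
        mx <- tapply(noise$height, key, max)
        noise <- noise[keep, , drop = FALSE]
        noise$height <- as.numeric(mx[paste(noise$dye, round(noise$size))])
    }
    pk <- rbind(rows, noise)
    pk <- pk[pk$height > 0, , drop = FALSE]
    tab <- PeakTable(sampleID, pk, metadata)
    # clip at the detector ceiling after bin merging, so no reported
    # peak can ever exceed saturation
    merged <- peaks(tab)
    merged$height <- pmin(merged$height, th@saturation)
    new("PeakTable", sampleID = tab@sampleID, peaks = merged,
        metadata = metadata)
}

#' Simulate a single-source sample
#'
#' Deterministic for a given seed. True-allele peak heights follow the
#' DNA-input response of the signal model (see the package vignette);
#' every STR allele peak is accompanied by one stutter peak exactly one
#' repeat unit (4 bp) shorter, with height ratio drawn from the locus's
#' stutter distribution truncated at zero. Baseline noise peaks (heights
#' uniform below the noise ceiling) are scattered across all channels;
#' every peak's size is jittered by at most 0.3 bp; heights clip at the
#' saturation ceiling. If \code{digestionFailure} is set on the genotype,
#' the control shows that enzyme's single-failure size and every marker
#' using the enzyme shows its uncut size regardless of allele.
#'
#' @param panel an \linkS4class{AssayPanel}.
#' @param genotype a \linkS4class{SampleGenotype} with concrete STR
#'   alleles.
#' @param seed integer seed.
#' @param sampleID sample identifier for the output table.
#' @return a \linkS4class{PeakTable}.
#' @examples
#' panel <- defaultPanel()
#' g <- makeGenotype(c282y = "var_hom", h63d = "het",
#'                   fga = c(20, 24), se33 = c(17, 29))
#' tab <- simulateSample(panel, g, seed = 1)
#' @export
simulateSample <- function(panel, genotype, seed,
                           sampleID = paste0("sim_", seed)) {
    stopifnot(is(genotype, "SampleGenotype"))
    for (l in panel@strLoci)
        if (is.null(genotype@strAlleles[[l@name]]))
            stop("genotype lacks STR alleles for ", l@name,
                 "; draw them or use simulateCohort()")
    set.seed(as.integer(seed))
    rows <- .expectedSignalRows(panel, genotype, genotype@dnaInput)
    .renderPeakTable(panel, rows, sampleID,
                     metadata = list(dna_input = genotype@dnaInput,
                                     seed = as.integer(seed),
                                     s65c = genotype@s65cStatus,
                                     digestion_failure =
                                         genotype@digestionFailure))
}

#' Simulate a blank (no-template) run
#'
#' Only baseline noise: every peak stays below the panel's noise ceiling
#' (50 RFU by default).
#'
#' @param panel an \linkS4class{AssayPanel}.
#' @param seed integer seed.
#' @param sampleID sample identifier.
#' @return a \linkS4class{PeakTable}.
#' @export
simulateBlank <- function(panel, seed, sampleID = paste0("blank_", seed)) {
    set.seed(as.integer(seed))
    .renderPeakTable(panel, NULL, sampleID,
                     metadata = list(blank = TRUE, seed = as.integer(seed)))
}

#' Simulate a two-person mixture
#'
#' Per-allele expected heights are proportional to each contributor's
#' template share: for a 1:r-denominator mixture (\code{ratio} = 1/denom,
#' the minor:major proportion) the minor contributes
#' \code{ratio / (1 + ratio)} of the total DNA input and the major the
#' rest. Shared alleles sum; a minor allele landing in a major allele's
#' stutter bin adds to the stutter peak height (the adversarial case for
#' contamination detection).
#'
#' @param panel an \linkS4class{AssayPanel}.
#' @param major,minor \linkS4class{SampleGenotype} contributors; the total
#'   DNA input and any digestion failure are taken from \code{major}.
#' @param ratio minor:major proportion in (0, 1]; 1:10 is
#'   \code{ratio = 0.1}.
#' @param seed integer seed.
#' @param sampleID sample identifier.
#' @return a \linkS4class{PeakTable}.
#' @export
simulateMixture <- function(panel, major, minor, ratio, seed,
                            sampleID = paste0("mix_", seed)) {
    stopifnot(is(major, "SampleGenotype"), is(minor, "SampleGenotype"))
    if (!(is.numeric(ratio) && length(ratio) == 1L && ratio > 0 &&
          ratio <= 1))
        stop("ratio (minor:major proportion) must lie in (0, 1]")
    set.seed(as.integer(seed))
    total <- major@dnaInput
    # a digestion failure is a property of the reaction, not a genotype:
    # the major contributor's flag governs the whole mix
    minor@digestionFailure <- major@digestionFailure
    rows <- rbind(
        .expectedSignalRows(panel, major, total / (1 + ratio)),
        .expectedSignalRows(panel, minor, total * ratio / (1 + ratio)))
    .renderPeakTable(panel, rows, sampleID,
                     metadata = list(dna_input = total, ratio = ratio,
                                     seed = as.integer(seed),
                                     mixture = sprintf("1:%g", 1 / ratio)))
}

#' The default 60-sample cohort composition
#'
#' Eight genotype classes totalling 60 samples (18/11/9/8/6/5/2/1),
#' reproducing the genotype spectrum of the assay's clinical validation
#' series: 18 fully reference samples, 11 H63D heterozygotes, 9 C282Y
#' heterozygotes, 8 compound C282Y/H63D heterozygotes, 6 C282Y variant
#' homozygotes, 5 H63D variant homozygotes, 2 S65C heterozygotes and 1
#' H63D+S65C double heterozygote.
#'
#' @param dnaInput DNA input in ng applied to every class (default 25).
#' @return list of \code{list(genotype = SampleGenotype, count = n)}
#'   entries; STR alleles are left unset for \code{\link{simulateCohort}}
#'   to draw.
#' @export
default60Composition <- function(dnaInput = 25) {
    cls <- list(
        list(c282y = "ref_hom", h63d = "ref_hom", s65c = "ref_hom", n = 18L),
        list(c282y = "ref_hom", h63d = "het",     s65c = "ref_hom", n = 11L),
        list(c282y = "het",     h63d = "ref_hom", s65c = "ref_hom", n = 9L),
        list(c282y = "het",     h63d = "het",     s65c = "ref_hom", n = 8L),
        list(c282y = "var_hom", h63d = "ref_hom", s65c = "ref_hom", n = 6L),
        list(c282y = "ref_hom", h63d = "var_hom", s65c = "ref_hom", n = 5L),
        list(c282y = "ref_hom", h63d = "ref_hom", s65c = "het",     n = 2L),
        list(c282y = "ref_hom", h63d = "het",     s65c = "het",     n = 1L))
    lapply(cls, function(x)
        list(genotype = makeGenotype(c282y = x$c282y, h63d = x$h63d,
                                     s65c = x$s65c, dnaInput = dnaInput),
             count = x$n))
}

#' Simulate a cohort of samples
#'
#' One peak table per sample; per-sample seeds are derived
#' deterministically from the master seed. STR genotypes missing from a
#' class template are drawn uniformly from each locus's integer allele
#' ladder.
#'
#' @param panel an \linkS4class{AssayPanel}.
#' @param composition list of \code{list(genotype =, count =)} entries,
#'   e.g. \code{\link{default60Composition}()}.
#' @param seed master integer seed.
#' @return list with elements \code{tables} (list of
#'   \linkS4class{PeakTable}) and \code{truth} (data.frame of generating
#'   genotypes per sample).
#' @export
simulateCohort <- function(panel, composition, seed) {
    if (!length(composition))
        return(list(tables = list(),
                    truth = data.frame(sample_id = character(),
                                       class = integer(),
                                       c282y = character(),
                                       h63d = character(),
                                       s65c = character())))
    counts <- vapply(composition, function(x) as.integer(x$count),
                     integer(1))
    stopifnot(all(counts > 0L))
    set.seed(as.integer(seed))
    n <- sum(counts)
    sampleSeeds <- sample.int(2^30, n)
    drawLadder <- function(locus)
        sample(seq.int(ceiling(locus@alleleMin), floor(locus@alleleMax)),
               2L, replace = TRUE)
    tables <- vector("list", n)
    truth <- vector("list", n)
    i <- 0L
    for (ci in seq_along(composition)) {
        template <- composition[[ci]]$genotype
        for (k in seq_len(counts[ci])) {
            i <- i + 1L
            g <- template
            for (l in panel@strLoci)
                if (is.null(g@strAlleles[[l@name]]))
                    g@strAlleles[[l@name]] <- drawLadder(l)
            id <- sprintf("S%03d", i)
            tables[[i]] <- simulateSample(panel, g, seed = sampleSeeds[i],
                                          sampleID = id)
            geno <- .rflpGenotypeLabels(panel, g)
            truth[[i]] <- data.frame(
                sample_id = id, class = ci, c282y = geno[["C282Y"]],
                h63d = geno[["H63D"]], s65c = g@s65cStatus,
                fga = paste(sort(g@strAlleles$FGA), collapse = "/"),
                se33 = paste(sort(g@strAlleles$SE33), collapse = "/"))
        }
    }
    list(tables = tables, truth = do.call(rbind, truth))
}

# translate allele states back to ref_hom/het/var_hom labels
.rflpGenotypeLabels <- function(panel, genotype) {
    out <- character()
    for (m in panel@rflpMarkers) {
        al <- genotype@rflpAlleles[[m@name]]
        if (is.null(al)) next
        v <- if (m@variantCreatesSite) "site_present" else "site_absent"
        nvar <- sum(al == v)
        out[[m@name]] <- c("ref_hom", "het", "var_hom")[nvar + 1L]
    }
    out
}
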