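test_that("deriveCutoff applies the multiplier and round-up rule", {
    blanks <- list(peakTab("FAM", c(100, 200), c(31, 50)),
                   peakTab("FAM", 150, 12))
    expect_identical(deriveCutoff(blanks, 5), 250)
    expect_identical(deriveCutoff(list(peakTab("FAM", 90, 43.2)), 5), 250)
    expect_identical(deriveCutoff(list(peakTab("FAM", 90, 31)), 5), 200)
    expect_error(deriveCutoff(list(), 5), "at least one")
    empty <- PeakTable("e", data.frame(dye = character(), size = numeric(),
                                       height = numeric()))
    expect_error(deriveCutoff(list(empty), 5), "no peaks")
})

test_that("filterPeaks is inclusive at the boundary and monotone", {
    tab <- peakTab("FAM", c(100, 110, 120), c(249, 250, 251))
    kept <- filterPeaks(tab, 250)
    expect_identical(peaks(kept)$height, c(250, 251))
    expect_identical(nrow(peaks(tab)), 3L)  # input unmodified
    expect_identical(peaks(filterPeaks(tab, 0.001)), peaks(tab))

    set.seed(33)
    for (i in 1:20) {
        rnd <- peakTab("FAM", sort(sample(60:400, 30)), runif(30, 0, 5000))
        cuts <- sort(runif(5, 1, 5000))
        kept <- vapply(cuts, function(ct)
            nrow(peaks(filterPeaks(rnd, ct))), integer(1))
        expect_true(all(diff(kept) <= 0))
    }
})

test_that("digestion-control validation distinguishes pass, fail and dropout", {
    panel <- testPanel()
    ok <- checkDigestionControls(peakTab("ATTO 550", c(114, 147),
                                         c(1500, 1500)), panel)
    expect_true(ok@amplificationOK)
    expect_identical(unname(ok@enzymeStatus[c("SexAI", "BspHI")]),
                     c("pass", "pass"))

    # SexAI failure: its single-failure product replaces the 114 peak
    fail <- checkDigestionControls(peakTab("ATTO 550", c(147, 171),
                                           c(1500, 1500)), panel)
    expect_identical(unname(fail@enzymeStatus["SexAI"]), "fail")
    expect_identical(unname(fail@enzymeStatus["BspHI"]), "pass")

    # fully uncut control: both enzymes failed
    uncut <- checkDigestionControls(peakTab("ATTO 550", 309, 2000), panel)
    expect_identical(unname(uncut@enzymeStatus), c("fail", "fail"))

    # empty control channel: amplification failure, both indeterminate
    blank <- checkDigestionControls(peakTab("FAM", 200, 5000), panel)
    expect_false(blank@amplificationOK)
    expect_identical(unname(blank@enzymeStatus),
                     c("indeterminate", "indeterminate"))

    # sub-cutoff control peaks do not count
    weak <- checkDigestionControls(peakTab("ATTO 550", c(114, 147),
                                           c(100, 100)), panel)
    expect_false(weak@amplificationOK)
})

test_that("marker calls follow the codominant rule table and control gate", {
    panel <- testPanel()
    marker <- rflpMarkers(panel)$C282Y  # cut 248, uncut 390
    pass <- new("ControlStatus", amplificationOK = TRUE,
                enzymeStatus = c(SexAI = "pass", BspHI = "pass"),
                evidence = c(114, 147))
    sexaiFail <- new("ControlStatus", amplificationOK = TRUE,
                     enzymeStatus = c(SexAI = "fail", BspHI = "pass"),
                     evidence = 147)
    callWith <- function(sizes, control) {
        callMarker(peakTab("ATTO 565", sizes, rep(3000, length(sizes))),
                   marker, control, 250, panel)
    }
    expect_identical(callWith(248, pass)@genotype, "var_hom")
    expect_identical(callWith(390, pass)@genotype, "ref_hom")
    expect_identical(callWith(c(248, 390), pass)@genotype, "het")

    gated <- callWith(390, sexaiFail)
    expect_identical(gated@genotype, "no_call")
    expect_identical(gated@reason, "control_fail")
    noPk <- callWith(600, pass)
    expect_identical(noPk@genotype, "no_call")
    expect_identical(noPk@reason, "no_peaks")

    noAmp <- new("ControlStatus", amplificationOK = FALSE,
                 enzymeStatus = c(SexAI = "indeterminate",
                                  BspHI = "indeterminate"),
                 evidence = numeric())
    expect_identical(callWith(248, noAmp)@reason, "amplification_fail")

    # polarity flip: with variant_creates_site FALSE the cut fragment is
    # the reference allele
    flipped <- marker
    flipped@variantCreatesSite <- FALSE
    expect_identical(
        callMarker(peakTab("ATTO 565", 248, 3000), flipped, pass, 250,
                   panel)@genotype, "ref_hom")
})

test_that("STR designation mapping handles microvariants, stutter and extras", {
    panel <- testPanel()
    fga <- strLoci(panel)$FGA
    o <- fga@sizeOffset

    hom <- callSTR(peakTab("FAM", o + 96, 4000), fga, 250)
    expect_identical(hom@alleles, 24)

    micro <- callSTR(peakTab("FAM", c(o + 96, o + 106), c(4000, 3900)),
                     fga, 250)
    expect_identical(micro@alleles, c(24, 26.2))

    # a peak one repeat below a taller peak is stutter, not an allele
    stut <- callSTR(peakTab("FAM", c(o + 92, o + 96), c(380, 4000)),
                    fga, 250)
    expect_identical(stut@alleles, 24)
    expect_length(stut@extraAlleles, 0L)

    # three surviving non-stutter peaks: two tallest called, one extra
    three <- callSTR(peakTab("FAM", o + c(80, 96, 120),
                             c(3500, 4000, 3000)), fga, 250)
    expect_identical(three@alleles, c(20, 24))
    expect_identical(three@extraAlleles, 30)

    # off-ladder peaks are recorded, never an error
    off <- callSTR(peakTab("FAM", c(o + 96, o + 300), c(4000, 3000)),
                   fga, 250)
    expect_identical(off@alleles, 24)
    expect_identical(off@offLadder, o + 300)
})

test_that("simulated samples are genotyped back to their generating truth", {
    panel <- testPanel()
    g <- makeGenotype(c282y = "var_hom", h63d = "het", fga = c(20, 24),
                      se33 = c(17, 29), dnaInput = 25, panel = panel)
    for (seed in 1:10) {
        rep <- genotypeSample(simulateSample(panel, g, seed), panel)
        expect_true(controlStatus(rep)@amplificationOK)
        expect_identical(markerCalls(rep)$C282Y@genotype, "var_hom")
        expect_identical(markerCalls(rep)$H63D@genotype, "het")
        expect_identical(strCalls(rep)$FGA@alleles, c(20, 24))
        expect_identical(strCalls(rep)$SE33@alleles, c(17, 29))
    }

    blankRep <- genotypeSample(simulateBlank(panel, 5), panel)
    expect_false(controlStatus(blankRep)@amplificationOK)
    for (mc in markerCalls(blankRep)) {
        expect_identical(mc@genotype, "no_call")
        expect_identical(mc@reason, "amplification_fail")
    }
    for (sc in strCalls(blankRep)) expect_length(sc@alleles, 0L)
})

test_that("whole-enzyme digestion failure always gates, never mistypes", {
    panel <- testPanel()
    # a C282Y variant homozygote whose SexAI digestion failed shows only
    # the uncut fragment -- exactly the dropout the control must catch
    g <- makeGenotype(c282y = "var_hom", h63d = "het", fga = c(20, 24),
                      se33 = c(17, 29), digestionFailure = "SexAI",
                      panel = panel)
    for (seed in 1:10) {
        rep <- genotypeSample(simulateSample(panel, g, seed), panel)
        expect_identical(controlStatus(rep)@enzymeStatus[["SexAI"]], "fail")
        cc <- markerCalls(rep)$C282Y
        expect_identical(cc@genotype, "no_call")
        expect_identical(cc@reason, "control_fail")
        # the BspHI-read marker is unaffected
        expect_identical(markerCalls(rep)$H63D@genotype, "het")
    }
})

test_that("S65C status never changes any call", {
    panel <- testPanel()
    for (s65c in c("het", "var_hom")) {
        a <- makeGenotype(h63d = "het", fga = c(20, 24), se33 = c(17, 29),
                          s65c = "ref_hom", panel = panel)
        b <- makeGenotype(h63d = "het", fga = c(20, 24), se33 = c(17, 29),
                          s65c = s65c, panel = panel)
        ta <- simulateSample(panel, a, seed = 9)
        tb <- simulateSample(panel, b, seed = 9)
        expect_equal(peaks(ta), peaks(tb))
        expect_identical(
            markerCalls(genotypeSample(ta, panel))$H63D@genotype,
            markerCalls(genotypeSample(tb, panel))$H63D@genotype)
    }
})

test_that("raising the cutoff only ever moves calls toward no_call", {
    panel <- testPanel()
    g <- makeGenotype(c282y = "het", h63d = "het", fga = c(20, 24),
                      se33 = c(17, 29), panel = panel)
    rank <- c(ref_hom = 1L, het = 1L, var_hom = 1L, no_call = 0L)
    for (seed in 1:5) {
        tab <- simulateSample(panel, g, seed)
        prev <- NULL
        for (cutoff in c(250, 500, 1000, 40000)) {
            rep <- genotypeSample(tab, panel, cutoff = cutoff)
            geno <- vapply(markerCalls(rep), slot, character(1),
                           "genotype")
            if (!is.null(prev)) {
                # a called genotype may only persist or drop out
                for (nm in names(geno))
                    expect_true(geno[[nm]] == prev[[nm]] ||
                                geno[[nm]] == "no_call")
            }
            prev <- geno
        }
    }
})
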