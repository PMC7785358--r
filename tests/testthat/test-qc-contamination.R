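# shared simulated material for the QC tests (built once per run)
qcStats <- local({
    cache <- NULL
    function(panel) {
        if (is.null(cache)) {
            pure <- simulateCohort(
                panel, list(list(genotype = makeGenotype(panel = panel),
                                 count = 120)), seed = 999)
            cache <<- estimateStutterStats(pure$tables, panel)
        }
        cache
    }
})

test_that("the stutter contamination threshold is mean + k SD", {
    stats <- data.frame(locus = c("FGA", "SE33"),
                        mean_ratio = c(0.080, 0.106),
                        sd_ratio = c(0.024, 0.024),
                        n_alleles = c(40L, 40L), usable = TRUE)
    thr <- stutterThreshold(stats, 2)
    expect_equal(unname(thr["FGA"]), 0.128)
    expect_equal(unname(thr["SE33"]), 0.154)
    expect_equal(unname(stutterThreshold(stats, 0)), stats$mean_ratio)

    stats$usable[2] <- FALSE
    expect_error(stutterThreshold(stats), "SE33")
})

test_that("stutter statistics estimate the generating parameters", {
    panel <- testPanel()
    # a small series comparable to a 40-allele calibration run
    sim <- simulateCohort(
        panel, list(list(genotype = makeGenotype(panel = panel),
                         count = 25)), seed = 271)
    st <- estimateStutterStats(sim$tables, panel)
    fga <- st[st$locus == "FGA", ]
    expect_true(fga$usable)
    expect_gte(fga$n_alleles, 40L)
    se <- fga$sd_ratio / sqrt(fga$n_alleles)
    expect_lt(abs(fga$mean_ratio - 0.080), 2 * se + 0.004)
})

test_that("zero and missing stutter bins enter the estimate as zero ratios", {
    panel <- testPanel()
    fga <- strLoci(panel)$FGA
    o <- fga@sizeOffset
    # two alleles with no stutter at all: mean ratio must be 0
    tab <- peakTab(c("FAM", "FAM", "ATTO 550", "ATTO 550"),
                   c(o + 96, o + 120, 114, 147),
                   c(4000, 3800, 1500, 1500))
    st <- estimateStutterStats(list(tab), panel)
    fgaRow <- st[st$locus == "FGA", ]
    expect_true(fgaRow$usable)
    expect_identical(fgaRow$mean_ratio, 0)

    # a single usable allele: unusable statistics, no crash
    one <- peakTab("FAM", o + 96, 4000)
    st1 <- estimateStutterStats(list(one), panel)
    expect_false(st1$usable[st1$locus == "FGA"])
    expect_error(stutterThreshold(st1[st1$locus == "FGA", ]), "FGA")
})

test_that("adversarial 1:10 mixtures are flagged, 1:100 are not", {
    panel <- testPanel()
    stats <- qcStats(panel)
    major <- makeGenotype(fga = c(20, 28), se33 = c(17, 25), panel = panel)
    # the minor contributor deliberately carries an FGA allele exactly one
    # repeat below a major allele, hiding in its stutter bin
    minor <- makeGenotype(h63d = "het", fga = c(19, 33), se33 = c(14, 30),
                          panel = panel)

    flagRate <- function(ratio, n = 40) {
        kinds <- character()
        hits <- 0L
        for (i in seq_len(n)) {
            tab <- simulateMixture(panel, major, minor, ratio,
                                   seed = 1e4 * (1 / ratio) + i)
            rep <- genotypeSample(tab, panel)
            cont <- suppressWarnings(
                detectContamination(rep, tab, stats, panel))
            if (isFlagged(cont)) {
                hits <- hits + 1L
                kinds <- union(kinds, evidence(cont)$kind)
            }
        }
        list(rate = hits / n, kinds = kinds)
    }
    r10 <- flagRate(0.1)
    expect_gt(r10$rate, 0.5)
    # detection rests on at least two independent evidence kinds
    expect_true(all(c("extra_str_allele", "elevated_stutter") %in%
                    r10$kinds))
    r100 <- flagRate(0.01)
    expect_lt(r100$rate, 0.5)
})

test_that("detection weakens monotonically with mixture dilution", {
    panel <- testPanel()
    stats <- qcStats(panel)
    major <- makeGenotype(fga = c(20, 28), se33 = c(17, 25), panel = panel)
    minor <- makeGenotype(h63d = "het", fga = c(19, 33), se33 = c(14, 30),
                          panel = panel)
    rate <- vapply(c(1, 10, 25, 100), function(denom) {
        hits <- 0L
        for (i in 1:40) {
            tab <- simulateMixture(panel, major, minor, 1 / denom,
                                   seed = 555 * denom + i)
            rep <- genotypeSample(tab, panel)
            if (isFlagged(suppressWarnings(
                detectContamination(rep, tab, stats, panel))))
                hits <- hits + 1L
        }
        hits / 40
    }, numeric(1))
    # majority-vote detection is monotone: positive at 1:1 and 1:10,
    # negative at 1:25 and 1:100
    expect_identical(rate >= 0.5, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("pure samples carry no extra-allele evidence", {
    panel <- testPanel()
    stats <- qcStats(panel)
    sim <- simulateCohort(
        panel, list(list(genotype = makeGenotype(panel = panel),
                         count = 30)), seed = 808)
    extra <- 0L
    for (tab in sim$tables) {
        rep <- genotypeSample(tab, panel)
        cont <- suppressWarnings(
            detectContamination(rep, tab, stats, panel))
        extra <- extra +
            sum(evidence(cont)$kind == "extra_str_allele")
    }
    expect_identical(extra, 0L)
})

test_that("the elevated-stutter false-positive rate stays near nominal", {
    panel <- testPanel()
    stats <- qcStats(panel)
    sim <- simulateCohort(
        panel, list(list(genotype = makeGenotype(panel = panel),
                         count = 120)), seed = 1234)
    flags <- 0L
    for (tab in sim$tables) {
        rep <- genotypeSample(tab, panel)
        if (isFlagged(suppressWarnings(
            detectContamination(rep, tab, stats, panel))))
            flags <- flags + 1L
    }
    # ~2.3% one-sided tail per measurable allele, union over up to four
    # alleles per sample plus occasional adjacent-allele het ambiguity:
    # the rate must stay well below a useful operating point
    expect_lt(flags / 120, 0.3)
})

test_that("identity matching multiplies Hardy-Weinberg genotype frequencies", {
    panel <- testPanel()
    mkReport <- function(fga, se33) {
        calls <- list(
            FGA = new("STRCall", locusName = "FGA", alleles = fga,
                      peakHeights = rep(1000, length(fga)),
                      extraAlleles = numeric(), extraHeights = numeric(),
                      offLadder = numeric()),
            SE33 = new("STRCall", locusName = "SE33", alleles = se33,
                       peakHeights = rep(1000, length(se33)),
                       extraAlleles = numeric(), extraHeights = numeric(),
                       offLadder = numeric()))
        new("SampleReport", sampleID = "x",
            control = new("ControlStatus", amplificationOK = TRUE,
                          enzymeStatus = c(SexAI = "pass", BspHI = "pass"),
                          evidence = numeric()),
            markerCalls = list(), strCalls = calls, contamination = NULL)
    }
    freqs <- data.frame(
        locus = rep(c("FGA", "SE33"), each = 2),
        allele = c(20, 24, 17, 29),
        freq = c(0.1, 0.1, 0.1, 0.1))

    a <- mkReport(c(20, 24), c(17, 29))
    res <- matchSamples(a, mkReport(c(20, 24), c(17, 29)), freqs)
    expect_true(res@match)
    expect_identical(res@comparedLoci, 2L)
    # two heterozygous loci at p = q = 0.1: (2 * 0.1 * 0.1)^2 = 4e-4
    expect_equal(res@matchProbability, 4e-4)

    differs <- matchSamples(a, mkReport(c(20, 26), c(17, 29)), freqs)
    expect_false(differs@match)

    # probability is a per-locus product, invariant to locus order
    hom <- matchSamples(mkReport(c(20, 20), c(17, 29)),
                        mkReport(c(20, 20), c(17, 29)), freqs)
    expect_equal(hom@matchProbability, 0.1^2 * (2 * 0.1 * 0.1))

    expect_error(
        matchSamples(a, mkReport(c(20, 24), c(17, 29)),
                     freqs[freqs$locus == "FGA", ]), "SE33")
})

test_that("the bundled synthetic frequency table supports identity checks", {
    freqs <- readFrequencyTable()
    expect_true(all(c("locus", "allele", "freq") %in% names(freqs)))
    expect_setequal(unique(freqs$locus), c("FGA", "SE33"))
    for (l in c("FGA", "SE33"))
        expect_equal(sum(freqs$freq[freqs$locus == l]), 1, tolerance = 0.01)
})
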