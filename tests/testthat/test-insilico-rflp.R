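test_that("findSites matches direct pattern arithmetic", {
    bsphi <- Enzyme("BspHI", "TCATGA", 1)
    sexai <- Enzyme("SexAI", "ACCWGGT", 1)
    expect_identical(findSites("GGTCATGAGG", bsphi), 3L)
    expect_identical(findSites("GGACCAGGTCC", sexai), 3L)  # W = A
    expect_identical(findSites("GGACCTGGTCC", sexai), 3L)  # W = T
    expect_identical(findSites("ACGTACGT", sexai), integer())
    expect_error(findSites("ACGTN", bsphi), "ACGT")
    expect_error(findSites("acgt", bsphi), "ACGT")
})

test_that("findSites equals the brute-force IUPAC-expansion oracle", {
    enzymes <- list(Enzyme("SexAI", "ACCWGGT", 1),
                    Enzyme("BspHI", "TCATGA", 1),
                    # non-palindromic and ambiguity-rich patterns
                    # exercise the reverse-strand path
                    Enzyme("TestA", "GGTCTC", 1),
                    Enzyme("TestB", "AYGGA", 2),
                    Enzyme("TestC", "CANNTG", 3))
    set.seed(101)
    lengths <- c(rep(500L, 120L), rep(2000L, 15L))
    for (n in lengths) {
        s <- randomSeq(n)
        for (e in enzymes) {
            expect_identical(findSites(s, e),
                             bruteForceCuts(s, e@recognition, e@cutOffset),
                             info = paste(e@name, "on", n, "bp"))
        }
    }
})

test_that("palindromic enzymes give mirror-image cuts on the reverse complement", {
    set.seed(7)
    enz <- list(Enzyme("SexAI", "ACCWGGT", 1), Enzyme("BspHI", "TCATGA", 1))
    for (i in 1:25) {
        s <- randomSeq(800)
        rc <- revcompChr(s)
        for (e in enz) {
            L <- nchar(e@recognition)
            cuts <- findSites(s, e)
            mirrored <- sort(nchar(s) - L + 2L * e@cutOffset - cuts)
            expect_identical(findSites(rc, e), as.integer(mirrored))
        }
    }
})

test_that("digestion partitions the amplicon and labels only terminal fragments", {
    panel <- testPanel()
    tpl <- buildFixtureTemplates(panel, seed = 1)
    enz <- enzymes(panel)

    frg <- digestAmplicon(tpl$FZD1$control, enz)
    expect_identical(frg$length, c(114L, 48L, 147L))
    labeled <- frg[!is.na(frg$dye), ]
    expect_setequal(labeled$length, c(114, 147))
    expect_true(all(labeled$dye == "ATTO 550"))
    expect_true(is.na(frg$dye[2]))  # the middle fragment is dark

    # no enzymes: one full-length fragment labeled at both ends
    whole <- digestAmplicon(tpl$FZD1$control, list())
    expect_identical(nrow(whole), 1L)
    expect_identical(whole$length, 309L)
    expect_identical(whole$dye5, "ATTO 550")
    expect_identical(whole$dye3, "ATTO 550")

    # conservation over every enzyme subset, every fixture amplicon
    subsets <- list(list(), enz[1], enz[2], enz)
    for (marker in names(tpl))
        for (allele in names(tpl[[marker]]))
            for (ss in subsets) {
                amp <- tpl[[marker]][[allele]]
                frg <- digestAmplicon(amp, ss)
                expect_identical(sum(frg$length), nchar(amp@sequence))
            }
})

test_that("fixture templates honor the declared site layout", {
    panel <- testPanel()
    tpl <- buildFixtureTemplates(panel, seed = 1)
    enz <- enzymes(panel)

    for (m in rflpMarkers(panel)) {
        diag <- enz[[m@enzymeName]]
        other <- enz[[setdiff(names(enz), m@enzymeName)]]
        present <- tpl[[m@name]]$site_present@sequence
        absent <- tpl[[m@name]]$site_absent@sequence
        expect_identical(findSites(present, diag),
                         m@sitePosition + diag@cutOffset)
        expect_identical(findSites(absent, diag), integer())
        expect_identical(findSites(present, other), integer())
        expect_identical(findSites(absent, other), integer())
        expect_true(startsWith(present,
                               primerPairs(panel)[[m@primerPair]]@upperSeq))
        # the two alleles differ by a single base
        expect_identical(nchar(present), nchar(absent))
        expect_identical(sum(strsplit(present, "")[[1]] !=
                             strsplit(absent, "")[[1]]), 1L)
    }

    ctl <- controlFragment(panel)
    fz <- tpl$FZD1$control@sequence
    expect_identical(findSites(fz, enz$SexAI),
                     ctl@sexaiSiteStart + enz$SexAI@cutOffset)
    expect_identical(findSites(fz, enz$BspHI),
                     ctl@bsphiSiteStart + enz$BspHI@cutOffset)
})

test_that("the S65C stand-in never alters the BspHI digest", {
    panel <- testPanel()
    tpl <- buildFixtureTemplates(panel, seed = 4)
    enz <- enzymes(panel)
    ref <- tpl$H63D$site_absent
    var <- tpl$H63D$site_absent_s65c
    expect_false(identical(ref@sequence, var@sequence))
    expect_identical(digestAmplicon(ref, enz)$length,
                     digestAmplicon(var, enz)$length)
    # the mutable position sits outside the recognition hexamer
    pos <- attr(tpl$H63D, "s65c_position")
    m <- rflpMarkers(panel)$H63D
    expect_true(pos < m@sitePosition || pos >= m@sitePosition + 6L)
})

test_that("fixture filler varies with the seed but sizes do not", {
    panel <- testPanel()
    a <- buildFixtureTemplates(panel, seed = 1)
    b <- buildFixtureTemplates(panel, seed = 2)
    a2 <- buildFixtureTemplates(panel, seed = 1)
    expect_identical(a$FZD1$control@sequence, a2$FZD1$control@sequence)
    expect_false(identical(a$FZD1$control@sequence, b$FZD1$control@sequence))
    enz <- enzymes(panel)
    for (marker in names(a))
        for (allele in names(a[[marker]]))
            expect_identical(
                digestAmplicon(a[[marker]][[allele]], enz)$length,
                digestAmplicon(b[[marker]][[allele]], enz)$length)
})

test_that("predicted peak sizes follow the codominant size map", {
    panel <- testPanel()
    # fully site-free at both markers: only the two uncut amplicon sizes
    # in the HFE channel
    g <- makeGenotype(fga = c(20, 24), se33 = c(17, 29), panel = panel)
    sizes <- predictPeakSizes(panel, g)
    hfe <- sizes[sizes$dye == "ATTO 565", ]
    expect_setequal(hfe$size, c(208, 390))

    # heterozygote: both cut and uncut present
    g <- makeGenotype(c282y = "het", fga = c(20, 24), se33 = c(17, 29),
                      panel = panel)
    sizes <- predictPeakSizes(panel, g)
    expect_setequal(sizes$size[sizes$dye == "ATTO 565"], c(208, 248, 390))

    # FGA (20, 24) with unit 4 and offset o: {o + 20*4, o + 24*4}
    o <- strLoci(panel)$FGA@sizeOffset
    expect_setequal(sizes$size[sizes$dye == "FAM"], c(o + 80, o + 96))

    # homozygote sizes are a subset of the heterozygote's, per marker
    for (gt in list(c("ref_hom", "het"), c("var_hom", "het"))) {
        hom <- predictPeakSizes(panel, makeGenotype(
            c282y = gt[1], fga = c(20, 20), se33 = c(17, 17), panel = panel))
        het <- predictPeakSizes(panel, makeGenotype(
            c282y = gt[2], fga = c(20, 24), se33 = c(17, 29), panel = panel))
        expect_true(all(hom$size[hom$dye == "ATTO 565"] %in%
                        het$size[het$dye == "ATTO 565"]))
    }

    # control double-digest sizes always contribute
    expect_setequal(sizes$size[sizes$dye == "ATTO 550"], c(114, 147))

    expect_error(predictPeakSizes(panel, makeGenotype(
        fga = c(5, 20), se33 = c(17, 29), panel = panel)), "range")
})

test_that("fixture templates export to FASTA and read back", {
    panel <- testPanel()
    tpl <- buildFixtureTemplates(panel, seed = 1)
    path <- withr::local_tempfile(fileext = ".fasta")
    exportTemplates(tpl, path)
    seqs <- Biostrings::readDNAStringSet(path)
    expect_true("FZD1|control" %in% names(seqs))
    expect_identical(as.character(seqs[["FZD1|control"]]),
                     tpl$FZD1$control@sequence)
    expect_identical(as.character(seqs[["C282Y|site_present"]]),
                     tpl$C282Y$site_present@sequence)
})
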