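# internal helpers

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
            R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
            B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

.revComp <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

.assertDNA <- function(x, what = "sequence") {
    if (length(x) != 1L || is.na(x) || !grepl("^[ACGT]+$", x))
        stop(what, " must be a non-empty uppercase ACGT string", call. = FALSE)
    invisible(x)
}

# bases compatible with one IUPAC pattern character
.iupacBases <- function(ch) strsplit(.IUPAC[[ch]], "")[[1]]

# deterministic per-sample seed derivation, kept below 2^31
.deriveSeed <- function(master, i) {
    as.integer((as.numeric(master) %% 99991) * 20011 + i * 7 + 1)
}

# STR designation <-> fragment size on the locus ladder
.strSize <- function(locus, designation) {
    rep <- floor(designation + 1e-9)
    rem <- round((designation - rep) * 10)
    locus@sizeOffset + locus@repeatUnitLength * rep + rem
}

.strDesignation <- function(locus, size) {
    rel <- round(size) - locus@sizeOffset
    rep <- rel %/% locus@repeatUnitLength
    rem <- rel %% locus@repeatUnitLength
    rep + rem / 10
}

# labeled cut-fragment size of an RFLP marker
.markerCutSize <- function(panel, marker) {
    enz <- panel@enzymes[[marker@enzymeName]]
    if (marker@labeledEnd == "five_prime")
        marker@sitePosition + enz@cutOffset
    else
        marker@ampliconLength - (marker@sitePosition + enz@cutOffset)
}

.markerUncutSize <- function(marker) marker@ampliconLength
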