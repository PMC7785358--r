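# independent brute-force oracle for restriction-site scanning: expands
# the IUPAC pattern into its concrete sequences and string-searches each,
# on both strands, with the same window/cut conventions as the contract

.iupacTable <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

expandIUPAC <- function(pattern) {
    chars <- strsplit(pattern, "")[[1]]
    combos <- expand.grid(lapply(chars, function(ch) .iupacTable[[ch]]),
                          stringsAsFactors = FALSE)
    apply(combos, 1L, paste, collapse = "")
}

revcompChr <- function(s)
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))

bruteForceCuts <- function(sequence, recognition, cutOffset) {
    fwd <- expandIUPAC(recognition)
    rev <- unique(vapply(fwd, revcompChr, character(1)))
    L <- nchar(recognition)
    n <- nchar(sequence)
    cuts <- integer()
    if (n >= L) {
        for (i in seq_len(n - L + 1L)) {
            win <- substr(sequence, i, i + L - 1L)
            s0 <- i - 1L
            if (win %in% fwd)
                cuts <- c(cuts, s0 + cutOffset)
            else if (win %in% rev)
                cuts <- c(cuts, s0 + L - cutOffset)
        }
    }
    sort(unique(as.integer(cuts)))
}
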