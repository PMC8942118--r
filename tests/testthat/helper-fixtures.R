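suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
})

# named GRanges shorthand
gr6 <- function(chrom, start1, end1, name, strand = "*", assembly = NA) {
    g <- GRanges(chrom, IRanges(start1, end1), strand = strand)
    names(g) <- name
    S4Vectors::metadata(g)$assembly <- assembly
    g
}

fragSet <- function(chrom, start1, end1, librarySize = NULL,
                    source = "test") {
    g <- if (length(chrom)) GRanges(chrom, IRanges(start1, end1))
         else GRanges()
    if (is.null(librarySize)) librarySize <- length(g)
    new("FragmentSet", fragments = g, librarySize = librarySize,
        source = source)
}

# Minimal SAM writer. `records` is a data.frame with columns
# qname, flag, rname, pos (1-based), cigar; seq/qual are left out ("*").
writeSAM <- function(records, seqinfo, path) {
    hdr <- c("@HD\tVN:1.6",
             paste0("@SQ\tSN:", names(seqinfo), "\tLN:", seqinfo))
    body <- with(records,
                 paste(qname, flag, rname, pos, 60L, cigar, "*", 0L, 0L,
                       "*", "*", sep = "\t"))
    writeLines(c(hdr, body), path)
    path
}

# Brute-force O(F x R) interval intersection counter (the independent
# counting oracle). Windows given 1-based inclusive.
bruteCount <- function(fragChrom, fragStart, fragEnd,
                       winChrom, winStart, winEnd) {
    vapply(seq_along(winChrom), function(i)
        sum(fragChrom == winChrom[i] &
            fragStart <= winEnd[i] & fragEnd >= winStart[i]),
        0L)
}

# Brute-force all-offset PWM scorer (the independent motif oracle):
# returns + strand scores at every 1-based offset.
bruteScores <- function(seq, pwm) {
    lo <- logOdds(pwm)
    w <- ncol(lo)
    chars <- strsplit(seq, "")[[1L]]
    n <- length(chars) - w + 1L
    if (n < 1L) return(numeric(0))
    vapply(seq_len(n), function(o) {
        s <- 0
        for (j in seq_len(w)) {
            b <- chars[o + j - 1L]
            if (b %in% c("A", "C", "G", "T"))
                s <- s + lo[b, j]
        }
        s
    }, 0)
}

# random DNA string
randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")

# One shared full synthetic genome (sequence included) for motif and
# acceptance tests; built once per test run.
.simCache <- new.env(parent = emptyenv())
sharedSim <- function() {
    if (is.null(.simCache$sim))
        .simCache$sim <- makeGenome(simConfig(seed = 20260920L))
    .simCache$sim
}
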