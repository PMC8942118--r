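.IUPAC <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.BASES <- c("A", "C", "G", "T")

# Default hit-reporting threshold on the exact tail p-value. Chosen so that
# the least informative bundled motif (the A-box, whose perfect-match tail
# probability under a uniform background is (1/4)^5 * (1/2)^3 ~= 1.22e-4)
# remains reportable, while a bare 5-bp half-site (max-score tail ~9.8e-4)
# can never reach significance -- a 5-mer simply carries too little
# information to be called against a 4-letter background.
DEFAULT_MIN_P <- 5e-4

# Exact distribution of the total log-odds score of a background-generated
# w-mer, by dynamic programming on a discretized score lattice. The
# reported granularity is scoreRange/1000; internally the lattice step is
# that granularity divided by the motif width, so the accumulated rounding
# error stays below one reported bin.
.pwmScoreDist <- function(logOdds, background, nbins = 1000L) {
    w <- ncol(logOdds)
    lo <- sum(apply(logOdds, 2L, min))
    hi <- sum(apply(logOdds, 2L, max))
    grain <- (hi - lo) / nbins
    if (grain < 1e-12) {
        return(list(grain = 0, minScore = lo, step = 0,
                    scores = lo, tail = 1))
    }
    step <- grain / w
    # per-column integer offsets from the column minimum
    colmin <- apply(logOdds, 2L, min)
    K <- as.integer(round((hi - lo) / step)) + w  # slack for rounding
    dist <- numeric(K + 1L)
    dist[1L] <- 1
    for (j in seq_len(w)) {
        idx <- as.integer(round((logOdds[, j] - colmin[j]) / step))
        nd <- numeric(K + 1L)
        for (b in 1:4) {
            p <- background[b]
            if (p == 0) next
            k <- idx[b]
            # shift dist by k bins, weight by p
            nd[(k + 1L):(K + 1L)] <- nd[(k + 1L):(K + 1L)] +
                p * dist[1:(K + 1L - k)]
        }
        dist <- nd
    }
    scores <- lo + (0:K) * step
    tail <- rev(cumsum(rev(dist)))
    list(grain = grain, minScore = lo, step = step,
         scores = scores, tail = tail)
}

# Tail lookup on the precomputed lattice; monotone non-increasing in s.
.distTail <- function(dist, s) {
    if (dist$step == 0)
        return(ifelse(s <= dist$minScore + 1e-12, 1, 0))
    k <- round((s - dist$minScore) / dist$step)
    k <- pmin(pmax(k, 0), length(dist$tail) - 1L)
    out <- dist$tail[k + 1L]
    out[s > dist$scores[length(dist$scores)] + dist$step / 2] <- 0
    out
}

.buildPWM <- function(name, probs, background, pseudocount) {
    logOdds <- log2(sweep(probs, 1L, background, "/"))
    pwm <- new("PWM", name = name, probs = probs, background = background,
               pseudocount = pseudocount, logOdds = logOdds,
               scoreDist = list())
    pwm@scoreDist <- .pwmScoreDist(logOdds, background)
    validObject(pwm)
    pwm
}

#' Build a PWM from an IUPAC consensus string
#'
#' Each consensus position contributes one count split equally over its
#' compatible bases; a pseudocount is added to every cell and columns are
#' renormalized. Fully degenerate positions ('N'/'n', e.g. the 3 bp spacer
#' of the palindromic ERE GGTCAnnnTGACC) equal the background and
#' contribute zero log-odds.
#'
#' @param consensus IUPAC string over A/C/G/T plus ambiguity codes
#'   (case-insensitive).
#' @param name Motif name (defaults to the consensus).
#' @param pseudocount Added per cell (default 0.25).
#' @param background Length-4 base probabilities (default uniform).
#' @return A [PWM-class].
#' @examples
#' ere <- consensusToPWM("GGTCANNNTGACC", name = "ERE")
#' motifWidth(ere)      # 13
#' logOdds(ere)[, 6:8]  # spacer columns: all zero
#' @export
consensusToPWM <- function(consensus, name = consensus, pseudocount = 0.25,
                           background = rep(0.25, 4)) {
    chars <- strsplit(toupper(consensus), "")[[1L]]
    bad <- setdiff(chars, names(.IUPAC))
    if (length(bad))
        stop("invalid consensus character(s): ",
             paste(unique(bad), collapse = ", "), call. = FALSE)
    probs <- vapply(chars, function(ch) {
        cnt <- stats::setNames(numeric(4), .BASES)
        compat <- .IUPAC[[ch]]
        cnt[compat] <- 1 / length(compat)
        p <- cnt + pseudocount
        p / sum(p)
    }, numeric(4))
    rownames(probs) <- .BASES
    .buildPWM(name, probs, background, pseudocount)
}

#' Build a PWM from a count (or probability) matrix
#'
#' @param counts 4 x width matrix, rows A, C, G, T (row names honoured if
#'   present). Columns of counts get the pseudocount added and are
#'   normalized.
#' @param name Motif name.
#' @param pseudocount Added per cell (default 0.25).
#' @param background Length-4 base probabilities (default uniform).
#' @return A [PWM-class].
#' @export
countsToPWM <- function(counts, name = "motif", pseudocount = 0.25,
                        background = rep(0.25, 4)) {
    counts <- as.matrix(counts)
    if (nrow(counts) != 4L)
        stop("counts must have 4 rows (A, C, G, T)", call. = FALSE)
    if (!is.null(rownames(counts)))
        counts <- counts[.BASES, , drop = FALSE]
    probs <- apply(counts + pseudocount, 2L, function(col) col / sum(col))
    rownames(probs) <- .BASES
    .buildPWM(name, probs, background, pseudocount)
}

#' Exact tail p-value of a PWM score
#'
#' Probability that a sequence of the motif's width, generated from the
#' background model, scores at least \code{score}. Computed from the exact
#' discretized score distribution carried by the PWM; monotone
#' non-increasing in \code{score}.
#'
#' @param pwm A [PWM-class].
#' @param score Numeric score(s) in bits.
#' @return p-value(s) in [0, 1].
#' @export
pwmPvalue <- function(pwm, score) {
    stopifnot(all(is.finite(score)))
    .distTail(pwm@scoreDist, score)
}

# Encode a DNA string as integer codes A=1 C=2 G=3 T=4, anything else 5.
.encodeDNA <- function(seq) {
    map <- integer(256); map[] <- 5L
    map[utf8ToInt("A")] <- 1L; map[utf8ToInt("C")] <- 2L
    map[utf8ToInt("G")] <- 3L; map[utf8ToInt("T")] <- 4L
    map[utf8ToInt("a")] <- 1L; map[utf8ToInt("c")] <- 2L
    map[utf8ToInt("g")] <- 3L; map[utf8ToInt("t")] <- 4L
    map[utf8ToInt(seq)]
}

#' Reverse complement of a DNA string
#'
#' @param seq Character scalar over A/C/G/T/N (case preserved as upper).
#' @return The reverse complement string.
#' @export
revComp <- function(seq) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Score every offset of an encoded sequence on the + strand.
# Positions coded 5 (N) contribute 0 bits (scored as background).
.scoreOffsets <- function(codes, logOdds) {
    w <- ncol(logOdds)
    L <- length(codes)
    if (L < w) return(numeric(0))
    n <- L - w + 1L
    s <- numeric(n)
    loExt <- rbind(logOdds, 0)   # 5th row: N
    loVec <- as.vector(loExt)
    for (j in seq_len(w))
        s <- s + loVec[codes[j:(j + n - 1L)] + 5L * (j - 1L)]
    s
}

#' Scan a sequence with a PWM
#'
#' Scores every offset of the sequence (and of its reverse complement for
#' minus-strand scanning) with the motif's log-odds matrix, assigns each
#' score an exact background tail p-value, and reports hits at
#' \code{p <= minP}. 'N' positions in the sequence score as background
#' (zero bits). Minus-strand hits are reported in forward coordinates: the
#' offset is the 0-based position of the leftmost matched base on the
#' forward strand.
#'
#' @param seq Character scalar (DNA).
#' @param pwm A [PWM-class].
#' @param strands \code{"both"} (default), \code{"+"} or \code{"-"}.
#' @param minP Report hits with p-value at or below this threshold
#'   (default \code{5e-4}, see package vignette for the rationale).
#' @return A data.frame of hits sorted by offset: \code{motif},
#'   \code{offset} (0-based), \code{strand}, \code{score} (bits),
#'   \code{p.value}.
#' @examples
#' ere <- consensusToPWM("GGTCANNNTGACC", name = "ERE")
#' s <- paste0(strrep("A", 40), "GGTCATTTTGACC", strrep("C", 40))
#' scanSequence(s, ere)   # palindrome: one hit per strand at offset 40
#' @export
scanSequence <- function(seq, pwm, strands = c("both", "+", "-"),
                         minP = DEFAULT_MIN_P) {
    strands <- match.arg(strands)
    w <- motifWidth(pwm)
    L <- nchar(seq)
    empty <- data.frame(motif = character(), offset = integer(),
                        width = integer(), strand = character(),
                        score = numeric(), p.value = numeric())
    if (L < w) return(empty)
    res <- list()
    if (strands %in% c("both", "+")) {
        s <- .scoreOffsets(.encodeDNA(seq), logOdds(pwm))
        p <- .distTail(pwm@scoreDist, s)
        keep <- which(p <= minP)
        if (length(keep))
            res[["+"]] <- data.frame(motif = pwm@name, offset = keep - 1L,
                                     width = w, strand = "+",
                                     score = s[keep], p.value = p[keep])
    }
    if (strands %in% c("both", "-")) {
        rc <- revComp(seq)
        s <- .scoreOffsets(.encodeDNA(rc), logOdds(pwm))
        p <- .distTail(pwm@scoreDist, s)
        keep <- which(p <= minP)
        if (length(keep)) {
            fwdOffset <- L - w - (keep - 1L)   # leftmost base, fwd coords
            res[["-"]] <- data.frame(motif = pwm@name, offset = fwdOffset,
                                     width = w, strand = "-",
                                     score = s[keep], p.value = p[keep])
        }
    }
    if (length(res) == 0L) return(empty)
    out <- do.call(rbind, res)
    out <- out[order(out$offset, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Bundled motif set
#'
#' The four motifs interrogated around Pol III genes: the palindromic full
#' estrogen response element (ERE, GGTCAnnnTGACC), the GGTCA half site
#' (its TGACC complement is covered by two-strand scanning), and the tRNA
#' internal promoter A-box (TRGCNNARYNNG) and B-box (GTTCGANNC) consensus
#' elements.
#'
#' @param pseudocount,background Passed to [consensusToPWM()].
#' @return Named list of [PWM-class] objects: ERE, halfERE, Abox, Bbox.
#' @export
defaultMotifSet <- function(pseudocount = 0.25, background = rep(0.25, 4)) {
    list(
        ERE = consensusToPWM("GGTCANNNTGACC", "ERE", pseudocount,
                             background),
        halfERE = consensusToPWM("GGTCA", "halfERE", pseudocount,
                                 background),
        Abox = consensusToPWM("TRGCNNARYNNG", "Abox", pseudocount,
                              background),
        Bbox = consensusToPWM("GTTCGANNC", "Bbox", pseudocount, background)
    )
}

#' Scan gene neighborhoods for a motif set
#'
#' Extracts the +/-\code{flank} sequence around every region and scans it
#' with each motif on both strands. A motif is reported "found" for a
#' region iff at least one hit reaches \code{p <= minP}.
#'
#' @param genome \code{DNAStringSet} or FASTA path.
#' @param regions Named \code{GRanges}.
#' @param motifs Named list of [PWM-class] (default [defaultMotifSet()]).
#' @param flank Flank in bp on both sides (default 20000).
#' @param minP Significance threshold (default \code{5e-4}).
#' @return A list:
#' \describe{
#'   \item{found}{Logical matrix, regions x motifs.}
#'   \item{hits}{data.frame of all hits with the region name, the offset
#'     within the extracted sequence, and \code{relStart}: the 0-based
#'     offset of the hit start relative to the region start on the forward
#'     strand (negative = upstream of the region).}
#' }
#' @export
scanNeighborhood <- function(genome, regions, motifs = defaultMotifSet(),
                             flank = 20000L, minP = DEFAULT_MIN_P) {
    validateRegions(regions)
    if (is.character(genome) && length(genome) == 1L)
        genome <- Biostrings::readDNAStringSet(genome)
    if (is.null(names(motifs)))
        names(motifs) <- vapply(motifs, function(m) m@name, "")
    found <- matrix(FALSE, nrow = length(regions), ncol = length(motifs),
                    dimnames = list(names(regions), names(motifs)))
    allhits <- list()
    seqs <- extractSequence(genome, regions, flank = flank)
    # actual left clip per region (flank may exceed chromosome bounds)
    leftFlank <- pmin(start(regions) - 1L, as.integer(flank))
    for (i in seq_along(regions)) {
        codes <- seqs[[i]]
        for (m in names(motifs)) {
            h <- scanSequence(codes, motifs[[m]], "both", minP)
            if (nrow(h)) {
                found[i, m] <- TRUE
                h$region <- names(regions)[i]
                h$relStart <- h$offset - leftFlank[i]
                allhits[[length(allhits) + 1L]] <- h
            }
        }
    }
    hits <- if (length(allhits)) do.call(rbind, allhits) else
        data.frame(motif = character(), offset = integer(),
                   width = integer(), strand = character(),
                   score = numeric(), p.value = numeric(),
                   region = character(), relStart = integer())
    rownames(hits) <- NULL
    list(found = found, hits = hits)
}

#' Write motif hits as a GFF3-like TSV
#'
#' @param hits Hit data.frame from [scanNeighborhood()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeMotifHits <- function(hits, path) {
    out <- data.frame(seqid = hits$region, source = "pol3occ",
                      motif = hits$motif, start = hits$relStart,
                      end = hits$relStart + hits$width,
                      score = hits$score, strand = hits$strand,
                      p_value = hits$p.value)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
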