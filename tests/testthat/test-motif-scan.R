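test_that("consensus-to-PWM arithmetic matches hand calculation", {
    # single 'A' with pseudocount 0.25 under a uniform background:
    # (1 + 0.25) / (1 + 4 * 0.25) = 0.625; log2(0.625/0.25) = 1.3219
    p <- consensusToPWM("A")
    expect_equal(unname(p@probs[, 1L]), c(0.625, 0.125, 0.125, 0.125))
    expect_equal(logOdds(p)["A", 1L], log2(0.625 / 0.25),
                 tolerance = 1e-12)
    # fully degenerate column equals the background, zero log-odds
    n <- consensusToPWM("N")
    expect_equal(unname(n@probs[, 1L]), rep(0.25, 4))
    expect_true(all(logOdds(n) == 0))
    # the palindromic full ERE: 13 columns, uniform spacer at 6-8
    ere <- consensusToPWM("GGTCAnnnTGACC")
    expect_equal(motifWidth(ere), 13L)
    for (j in 6:8)
        expect_equal(unname(ere@probs[, j]), rep(0.25, 4))
    # two-base ambiguity codes split the count
    r <- consensusToPWM("R")
    expect_equal(unname(r@probs[, 1L]),
                 c(0.75, 0.25, 0.75, 0.25) / 2)
    expect_error(consensusToPWM("GXT"), "invalid consensus")
})

test_that("score distribution bounds give p = 0 and p = 1", {
    pwm <- consensusToPWM("GGTCA")
    smax <- sum(apply(logOdds(pwm), 2L, max))
    smin <- sum(apply(logOdds(pwm), 2L, min))
    expect_equal(pwmPvalue(pwm, smax + 1), 0)
    expect_equal(pwmPvalue(pwm, smin - 1), 1)
    expect_equal(pwmPvalue(pwm, smin), 1)
})

test_that("DP tail matches exhaustive k-mer enumeration for widths 4-6", {
    kmers <- function(w) {
        g <- do.call(expand.grid,
                     rep(list(c("A", "C", "G", "T")), w))
        apply(g, 1L, paste, collapse = "")
    }
    for (cons in c("GGTC", "GGTCA", "GGTCAN", "RYGACN")) {
        pwm <- consensusToPWM(cons)
        w <- motifWidth(pwm)
        lo <- logOdds(pwm)
        all.s <- vapply(strsplit(kmers(w), ""), function(ch)
            sum(lo[cbind(match(ch, c("A", "C", "G", "T")),
                         seq_len(w))]), 0)
        grain <- pwm@scoreDist$grain
        grid <- seq(min(all.s), max(all.s), length.out = 25L)
        for (s in grid) {
            pEnum <- mean(all.s >= s)
            pDp <- pwmPvalue(pwm, s)
            # the DP lattice may shift a score by at most one reported bin
            lov <- mean(all.s >= s + grain)
            hiv <- mean(all.s >= s - grain)
            expect_gte(pDp, lov)
            expect_lte(pDp, hiv)
            expect_lt(abs(pDp - pEnum), max(hiv - lov, 1e-12) + 1e-12)
        }
        # monotone non-increasing
        ps <- pwmPvalue(pwm, grid)
        expect_true(all(diff(ps) <= 1e-12))
    }
})

test_that("scanning equals the all-offset brute-force scorer", {
    set.seed(31)
    ere <- consensusToPWM("GGTCANNNTGACC", "ERE")
    for (rep in 1:10) {
        s <- randSeq(1000)
        hits <- scanSequence(s, ere, strands = "+", minP = 0.01)
        ref <- bruteScores(s, ere)
        pref <- pwmPvalue(ere, ref)
        expect_equal(hits$offset, which(pref <= 0.01) - 1L)
        expect_equal(hits$score, ref[pref <= 0.01], tolerance = 1e-12)
        # minus-strand scan equals brute force on the reverse complement
        hitsM <- scanSequence(s, ere, strands = "-", minP = 0.01)
        refM <- bruteScores(revComp(s), ere)
        prefM <- pwmPvalue(ere, refM)
        expect_equal(sort(hitsM$offset),
                     sort(1000 - 13 - (which(prefM <= 0.01) - 1L)))
    }
})

test_that("planted ERE and its reverse complement are recovered at the
           planted offset", {
    set.seed(32)
    ere <- consensusToPWM("GGTCANNNTGACC", "ERE")
    core <- "GGTCAAAATGACC"
    bg <- randSeq(1000)
    # scrub chance near-hits so the plant is the only signal
    while (nrow(scanSequence(bg, ere, minP = 1e-4)) > 0L)
        bg <- randSeq(1000)
    planted <- paste0(substr(bg, 1, 400), core, substr(bg, 414, 1000))
    h <- scanSequence(planted, ere, minP = 1e-4)
    expect_true(any(h$offset == 400L & h$strand == "+"))
    plantedRC <- paste0(substr(bg, 1, 400), revComp(core),
                        substr(bg, 414, 1000))
    h2 <- scanSequence(plantedRC, ere, minP = 1e-4)
    expect_true(any(h2$offset == 400L & h2$strand == "-"))
})

test_that("strand symmetry: minus-strand hits equal plus-strand hits on the
           reverse complement", {
    set.seed(33)
    bbox <- consensusToPWM("GTTCGANNC", "Bbox")
    for (rep in 1:5) {
        s <- randSeq(600)
        minus <- scanSequence(s, bbox, strands = "-", minP = 0.005)
        plusRC <- scanSequence(revComp(s), bbox, strands = "+",
                               minP = 0.005)
        # transform revcomp offsets into forward coordinates
        expect_setequal(minus$offset, 600 - 9 - plusRC$offset)
        expect_equal(sort(minus$score), sort(plusRC$score),
                     tolerance = 1e-12)
    }
})

test_that("a palindromic PWM scores both strands identically", {
    set.seed(34)
    ere <- consensusToPWM("GGTCANNNTGACC", "ERE")
    s <- randSeq(500)
    both <- scanSequence(s, ere, strands = "both", minP = 0.02)
    plus <- both[both$strand == "+", ]
    minus <- both[both$strand == "-", ]
    expect_equal(plus$offset, minus$offset)
    expect_equal(plus$score, minus$score, tolerance = 1e-9)
})

test_that("hit calls agree with Biostrings::matchPWM as an independent
           reference", {
    set.seed(35)
    cons <- "TGACGTCA"
    pwm <- consensusToPWM(cons)
    s <- paste0(randSeq(300), cons, randSeq(300))
    # matchPWM works on probability matrices with its own min.score scale;
    # at 95% of the maximal score both implementations must call the plant
    hits <- scanSequence(s, pwm, strands = "+", minP = 1e-4)
    ref <- Biostrings::matchPWM(log2(pwm@probs / 0.25),
                                Biostrings::DNAString(s),
                                min.score = "95%")
    expect_true(300L %in% hits$offset)
    expect_true(301L %in% BiocGenerics::start(ref))
    expect_true(all(BiocGenerics::start(ref) - 1L %in% hits$offset))
})

test_that("sequences shorter than the motif yield an empty result and N
           scores as background", {
    ere <- consensusToPWM("GGTCANNNTGACC")
    expect_equal(nrow(scanSequence("GGTCA", ere)), 0L)
    # an N inside an otherwise perfect site loses that column's bits only
    perfect <- "GGTCAAAATGACC"
    withN <- "GGTCAAAATGACN"
    s1 <- bruteScores(perfect, ere)[1L]
    s2 <- bruteScores(withN, ere)[1L]
    expect_equal(s1 - s2, logOdds(ere)["C", 13L])
    h <- scanSequence(withN, ere, strands = "+", minP = 1)
    expect_equal(h$score[h$offset == 0L], s2, tolerance = 1e-12)
})

test_that("neighborhood scanning reports planted tRNA promoter elements and
           the control ERE, and no ERE near tDNAs", {
    sim <- sharedSim()
    # a manageable subset of tDNAs here; the full sweep runs in the
    # acceptance suite
    idx <- seq(1L, length(sim@tdna), by = 20L)
    res <- scanNeighborhood(sim@sequence, sim@tdna[idx], flank = 20000L)
    expect_true(all(res$found[, "Abox"]))
    expect_true(all(res$found[, "Bbox"]))
    expect_true(all(!res$found[, "ERE"]))
    expect_true(all(!res$found[, "halfERE"]))
    # A-box hit at the planted offset in every scanned tDNA
    tr <- sim@truth[match(rownames(res$found), sim@truth$name), ]
    ab <- res$hits[res$hits$motif == "Abox", ]
    for (i in seq_along(idx)) {
        nm <- rownames(res$found)[i]
        reg <- sim@tdna[nm]
        relExp <- if (as.character(strand(reg)) == "-")
            width(reg) - 1L - tr$aboxRel[i] - 11L else tr$aboxRel[i]
        expect_true(any(ab$region == nm & ab$relStart == relExp))
    }
    # control locus: ERE found at -585 relative to the gene start
    ctrl <- scanNeighborhood(sim@sequence, sim@control["GREB1like"],
                             flank = 20000L)
    expect_true(ctrl$found["GREB1like", "ERE"])
    ereHits <- ctrl$hits[ctrl$hits$motif == "ERE", ]
    expect_true(all(ereHits$relStart == -585L))
})
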