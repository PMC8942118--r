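#' Simulation configuration
#'
#' Parameters of the synthetic genome and ChIP libraries. Defaults describe
#' the reference study conditions used throughout the package's tests: 400
#' tDNAs of which half are bound at 8-fold window enrichment, a 2e6-fragment
#' library, and Q-value scales matching short-read human ChIP-seq (the
#' library is spread over an effective mappable genome of 2.45 Gb, of which
#' only the annotated neighborhoods are instantiated as sequence; stored
#' fragments are those landing on the instantiated chromosomes while
#' \code{librarySize} counts the whole library).
#'
#' @param nChromosomes Number of autosome-like chromosomes (default 4).
#' @param chromosomeLength Length of each, bp (default 4.8e6).
#' @param nTdna,nSnorna,nMirna Locus counts (defaults 400, 100, 100).
#' @param enrichedFraction Fraction of tDNAs bound (default 0.5).
#' @param enrichmentFactor Fold excess of expected fragment count in the
#'   +/-500 bp window at bound loci over background (default 8).
#' @param librarySize Fragments in the library (default 2e6).
#' @param fragmentLengthMean,fragmentLengthSd Fragment length model, bp
#'   (defaults 200, 40; truncated at 50).
#' @param peakSd Gaussian spread of ChIP enrichment around the gene start,
#'   bp (default 300, so a +/-500 bp window captures ~90% of peak mass).
#' @param effectiveGenomeSize Mappable genome the library is spread over,
#'   bp (default 2.45e9, the uniquely mappable human genome at 36 bp
#'   reads).
#' @param offtargetFraction Library mass bound at canonical sites outside
#'   the simulated loci (virtual, contributes only to \code{librarySize};
#'   default 0).
#' @param controlLocus Plant control loci: a bound GREB1-like gene with a
#'   full ERE 585 bp upstream of its start, and an unbound BC200-like gene
#'   (default \code{TRUE}).
#' @param controlEnrichment Window enrichment factor of the GREB1-like
#'   locus (default 50; canonical ERE-driven targets tower over tDNA
#'   signal).
#' @param met3Boost Multiplier applied to bound-locus enrichment factors by
#'   the met3-like profile (default 3).
#' @param spacing Minimum distance between locus starts, bp (default
#'   25000, keeping +/-10 kb windows clean).
#' @param seed Seed for genome construction (default 1).
#' @return A validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nChromosomes = 4L, chromosomeLength = 4.8e6,
                      nTdna = 400L, nSnorna = 100L, nMirna = 100L,
                      enrichedFraction = 0.5, enrichmentFactor = 8,
                      librarySize = 2e6, fragmentLengthMean = 200,
                      fragmentLengthSd = 40, peakSd = 300,
                      effectiveGenomeSize = 2.45e9,
                      offtargetFraction = 0, controlLocus = TRUE,
                      controlEnrichment = 50, met3Boost = 3,
                      spacing = 25000L, seed = 1L) {
    cfg <- list(nChromosomes = as.integer(nChromosomes),
                chromosomeLength = as.numeric(chromosomeLength),
                nTdna = as.integer(nTdna), nSnorna = as.integer(nSnorna),
                nMirna = as.integer(nMirna),
                enrichedFraction = enrichedFraction,
                enrichmentFactor = enrichmentFactor,
                librarySize = librarySize,
                fragmentLengthMean = fragmentLengthMean,
                fragmentLengthSd = fragmentLengthSd, peakSd = peakSd,
                effectiveGenomeSize = effectiveGenomeSize,
                offtargetFraction = offtargetFraction,
                controlLocus = isTRUE(controlLocus),
                controlEnrichment = controlEnrichment,
                met3Boost = met3Boost, spacing = as.numeric(spacing),
                seed = as.integer(seed))
    stopifnot(cfg$enrichedFraction >= 0, cfg$enrichedFraction <= 1,
              cfg$enrichmentFactor >= 1, cfg$nTdna > 0, cfg$nSnorna >= 0,
              cfg$nMirna >= 0, cfg$librarySize > 0, cfg$peakSd > 0,
              cfg$offtargetFraction >= 0, cfg$offtargetFraction < 1,
              cfg$effectiveGenomeSize >=
                  cfg$nChromosomes * cfg$chromosomeLength)
    class(cfg) <- "SimConfig"
    cfg
}

# mismatching substitute for each base, used when scrubbing chance EREs
.MUTATE <- c(A = "C", C = "A", G = "T", T = "G")

# Remove chance ERE-like sites from a character-vector chromosome: scan at
# the default stringency, mutate one matching informative base per hit
# (outside protected footprints), iterate to convergence. The ERE is
# palindromic, so a plus-strand scan covers both orientations.
.scrubERE <- function(chars, protected, erePwm, minP) {
    consensusCode <- match(strsplit("GGTCANNNTGACC", "")[[1L]], .BASES)
    infoCols <- which(!is.na(consensusCode))
    w <- 13L
    L <- length(chars)
    codes <- match(chars, .BASES)
    codes[is.na(codes)] <- 5L
    # one full scan; after mutating, only the +/- w neighbourhood of a
    # mutated base can change, so re-check those windows locally
    s <- .scoreOffsets(codes, logOdds(erePwm))
    p <- .distTail(erePwm@scoreDist, s)
    pending <- which(p <= minP)
    mutateOne <- function(o) {
        # a mutation for an overlapping hit may have fixed this one already
        sv <- .scoreOffsets(codes[o:(o + w - 1L)], logOdds(erePwm))
        if (.distTail(erePwm@scoreDist, sv) > minP) return(o)
        pos <- o + infoCols - 1L
        matching <- codes[pos] == consensusCode[infoCols]
        cand <- pos[matching & !protected[pos]]
        if (length(cand) == 0L) cand <- pos[matching]
        tgt <- cand[1L]
        chars[tgt] <<- .MUTATE[[chars[tgt]]]
        codes[tgt] <<- match(chars[tgt], .BASES)
        tgt
    }
    guard <- 0L
    while (length(pending)) {
        guard <- guard + 1L
        if (guard > 50L)
            stop("ERE scrubbing did not converge", call. = FALSE)
        touched <- vapply(pending, mutateOne, 0L)
        # local re-check around every touched base
        lo <- pmax(1L, touched - (w - 1L))
        hi <- pmin(L - w + 1L, touched)
        pending <- integer(0)
        for (k in seq_along(touched)) {
            offs <- lo[k]:hi[k]
            win <- codes[lo[k]:(hi[k] + w - 1L)]
            sv <- .scoreOffsets(win, logOdds(erePwm))
            pv <- .distTail(erePwm@scoreDist, sv)
            pending <- c(pending, offs[pv <= minP])
        }
        pending <- unique(pending)
    }
    chars
}

# Instantiate an IUPAC consensus as a concrete sequence (random choice
# among compatible bases at degenerate positions).
.instantiate <- function(consensus) {
    vapply(strsplit(toupper(consensus), "")[[1L]],
           function(ch) sample(.IUPAC[[ch]], 1L), "")
}

# Genomic positions and forward-strand bases of a motif planted at a
# 0-based offset relative to a gene's 5' end, honouring gene strand.
# Assignment into the chromosome is left to the caller so the (large)
# sequence vector is modified in place rather than copied.
.plant <- function(geneStart1, geneEnd1, strand, rel0, motif) {
    w <- length(motif)
    if (strand == "-") {
        # rel0 measured 5'->3' from the gene start at `geneEnd1`
        list(gpos = (geneEnd1 - rel0) - (w - 1L):0L,  # ascending order
             vals = rev(chartr("ACGT", "TGCA", motif)))
    } else {
        list(gpos = geneStart1 + rel0 + 0:(w - 1L), vals = motif)
    }
}

#' Generate a synthetic genome with Pol III annotations and planted motifs
#'
#' Builds i.i.d. uniform background sequence, places tDNA, snoRNA and
#' miRNA loci with a minimum start-to-start spacing, plants A-box and
#' B-box internal promoter elements at fixed offsets downstream of every
#' tDNA start, scrubs chance ERE-like sites genome-wide (so that no full
#' ERE reaches the scanner's default stringency outside the control), and
#' plants a single full ERE 585 bp upstream of the GREB1-like control
#' locus on a dedicated control chromosome. Which tDNAs are bound (for the
#' mcf7/met3-like profiles) is drawn here so that all libraries simulated
#' from one genome share the truth.
#'
#' @param config A [simConfig()] list.
#' @param sequence Generate nucleotide sequence (default \code{TRUE}).
#'   With \code{FALSE} only coordinates, strands and the bound truth are
#'   built (sufficient for fragment simulation and occupancy analyses that
#'   do not touch sequence); the sequence slot is left empty.
#' @return A [SyntheticGenome-class].
#' @export
makeGenome <- function(config = simConfig(), sequence = TRUE) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    nLoci <- config$nTdna + config$nSnorna + config$nMirna
    margin <- 30000
    step <- config$spacing + 5000
    jitterMax <- 4000
    capacity <- floor((config$chromosomeLength - 2 * margin - jitterMax) /
                      step)
    if (capacity * config$nChromosomes < nLoci)
        stop("cannot place ", nLoci, " loci with ", config$spacing,
             " bp spacing on ", config$nChromosomes, " x ",
             config$chromosomeLength, " bp chromosomes", call. = FALSE)
    chromNames <- paste0("chr", seq_len(config$nChromosomes))
    # locus classes shuffled over placement slots
    cls <- sample(rep(c("tdna", "snorna", "mirna"),
                      c(config$nTdna, config$nSnorna, config$nMirna)))
    widths <- ifelse(cls == "tdna", sample(70:90, nLoci, replace = TRUE),
              ifelse(cls == "snorna", sample(100:150, nLoci, replace = TRUE),
                     sample(70:90, nLoci, replace = TRUE)))
    strands <- sample(c("+", "-"), nLoci, replace = TRUE)
    chromOf <- rep(chromNames, length.out = nLoci)
    slot <- integer(nLoci)
    for (ch in chromNames) {
        idx <- which(chromOf == ch)
        slot[idx] <- seq_along(idx)
    }
    start1 <- as.integer(margin + (slot - 1) * step +
                         floor(stats::runif(nLoci) * jitterMax)) + 1L
    end1 <- start1 + widths - 1L
    counters <- list(tdna = 0L, snorna = 0L, mirna = 0L)
    prefix <- c(tdna = "tRNA", snorna = "snoRNA", mirna = "miRNA")
    nm <- character(nLoci)
    for (i in seq_len(nLoci)) {
        counters[[cls[i]]] <- counters[[cls[i]]] + 1L
        nm[i] <- paste0(prefix[[cls[i]]], "-", counters[[cls[i]]])
    }
    # bound truth for the mcf7/met3-like profiles (drawn before any
    # sequence synthesis so truth is identical with sequence = FALSE)
    tdnaIdx <- which(cls == "tdna")
    nBound <- round(config$enrichedFraction * length(tdnaIdx))
    boundIdx <- sort(sample(tdnaIdx, nBound))
    # control chromosome coordinates
    ctrlName <- character(0)
    ctrlStart <- integer(0); ctrlEnd <- integer(0)
    ctrlLen <- 120000L
    ereRel <- NA_integer_
    if (config$controlLocus) {
        ctrlName <- c("GREB1like", "BC200like")
        ctrlStart <- c(30001L, 90001L)
        ctrlEnd <- c(32000L, 90200L)
        ereRel <- -585L
    }
    aboxRel <- 8L; bboxRel <- 52L
    truthAbox <- ifelse(cls == "tdna", aboxRel, NA_integer_)
    truthBbox <- ifelse(cls == "tdna", bboxRel, NA_integer_)
    seqs <- list()
    if (sequence) {
        # background sequence
        seqs <- lapply(chromNames, function(ch)
            sample(.BASES, config$chromosomeLength, replace = TRUE))
        names(seqs) <- chromNames
        protected <- lapply(chromNames, function(ch)
            logical(config$chromosomeLength))
        names(protected) <- chromNames
        # plant A-box and B-box in every tDNA, at classic
        # internal-promoter offsets downstream of the transcription start
        for (i in which(cls == "tdna")) {
            ch <- chromOf[i]
            pa <- .plant(start1[i], end1[i], strands[i], aboxRel,
                         .instantiate("TRGCNNARYNNG"))
            seqs[[ch]][pa$gpos] <- pa$vals
            protected[[ch]][pa$gpos] <- TRUE
            pb <- .plant(start1[i], end1[i], strands[i], bboxRel,
                         .instantiate("GTTCGANNC"))
            seqs[[ch]][pb$gpos] <- pb$vals
            protected[[ch]][pb$gpos] <- TRUE
        }
        if (config$controlLocus) {
            seqs[["chrCtrl"]] <- sample(.BASES, ctrlLen, replace = TRUE)
            protected[["chrCtrl"]] <- logical(ctrlLen)
        }
        # scrub chance EREs everywhere, then plant the one control ERE
        ere <- consensusToPWM("GGTCANNNTGACC", "ERE")
        for (ch in names(seqs))
            seqs[[ch]] <- .scrubERE(seqs[[ch]], protected[[ch]], ere,
                                    DEFAULT_MIN_P)
        if (config$controlLocus) {
            ereSeq <- strsplit("GGTCATATTGACC", "")[[1L]]  # fixed spacer
            gpos <- ctrlStart[1L] + ereRel + 0:12L
            seqs[["chrCtrl"]][gpos] <- ereSeq
        }
    }
    if (config$controlLocus)
        chromNames <- c(chromNames, "chrCtrl")
    truth <- data.frame(
        name = c(nm, ctrlName),
        class = c(cls, rep("control", length(ctrlName))),
        chrom = c(chromOf, rep("chrCtrl", length(ctrlName))),
        start = c(start1, ctrlStart), end = c(end1, ctrlEnd),
        strand = c(strands, rep("+", length(ctrlName))),
        bound = c(seq_len(nLoci) %in% boundIdx,
                  if (length(ctrlName)) c(TRUE, FALSE)),
        aboxRel = c(truthAbox, rep(NA_integer_, length(ctrlName))),
        bboxRel = c(truthBbox, rep(NA_integer_, length(ctrlName))),
        ereRel = c(rep(NA_integer_, nLoci),
                   if (length(ctrlName)) c(ereRel, NA_integer_)),
        stringsAsFactors = FALSE)
    mkRegions <- function(sel) {
        .makeRegions(truth$chrom[sel], truth$start[sel] - 1L,
                     truth$end[sel], truth$name[sel], truth$strand[sel],
                     assembly = "sim1")
    }
    dna <- Biostrings::DNAStringSet(
        vapply(seqs, paste, "", collapse = ""))
    cfgOut <- unclass(config)
    cfgOut$chromLengths <- stats::setNames(
        c(rep(config$chromosomeLength, config$nChromosomes),
          if (config$controlLocus) ctrlLen),
        chromNames)
    new("SyntheticGenome", sequence = dna,
        tdna = mkRegions(truth$class == "tdna"),
        snorna = mkRegions(truth$class == "snorna"),
        mirna = mkRegions(truth$class == "mirna"),
        control = mkRegions(truth$class == "control"),
        truth = truth, config = cfgOut)
}

#' Simulate a ChIP-seq fragment library over a synthetic genome
#'
#' Fragment midpoints are drawn from a mixture of uniform background over
#' the effective genome and per-bound-locus Gaussians (sd
#' \code{peakSd}) centred on the strand-aware locus start. Mixture weights
#' are calibrated so that a bound locus's expected +/-500 bp window count
#' (as measured by >= 1 bp overlap counting, i.e. over an effective window
#' of 1000 bp + one mean fragment length) equals \code{enrichmentFactor}
#' times the background expectation. Only fragments landing on the
#' instantiated chromosomes are stored; \code{librarySize} counts the whole
#' library. Fully seeded: identical genome + profile + seed reproduce the
#' library exactly.
#'
#' Profiles: \code{mcf7_like} (the genome's bound tDNA subset plus the
#' control locus), \code{mda_like} (only the control locus bound, library
#' 2e7 with 80% of mass at canonical off-target sites), \code{met3_like}
#' (as mcf7-like with bound-locus factors multiplied by \code{met3Boost}).
#'
#' @param sim A [SyntheticGenome-class] from [makeGenome()].
#' @param profile One of \code{"mcf7_like"}, \code{"mda_like"},
#'   \code{"met3_like"}.
#' @param seed Library seed (default 1).
#' @param librarySize Optional override of the profile's library size.
#' @return A list: \code{fragments} ([FragmentSet-class]), \code{truth}
#'   (locus truth with per-locus expected +/-500 bp window counts for this
#'   library), \code{profile}, \code{seed}.
#' @export
simulateChip <- function(sim, profile = c("mcf7_like", "mda_like",
                                          "met3_like"),
                         seed = 1L, librarySize = NULL) {
    stopifnot(is(sim, "SyntheticGenome"))
    profile <- match.arg(profile)
    cfg <- sim@config
    truth <- sim@truth
    N <- switch(profile,
                mcf7_like = cfg$librarySize,
                met3_like = cfg$librarySize,
                mda_like = 2e7)
    offtarget <- switch(profile, mda_like = 0.8, 0)
    if (!is.null(librarySize)) N <- as.numeric(librarySize)
    if (N <= 0) stop("librarySize must be > 0", call. = FALSE)
    boost <- if (profile == "met3_like") cfg$met3Boost else 1
    # per-locus enrichment factors for this profile
    f <- rep(1, nrow(truth))
    isCtrlBound <- truth$class == "control" & truth$bound
    if (profile %in% c("mcf7_like", "met3_like"))
        f[truth$class == "tdna" & truth$bound] <-
            cfg$enrichmentFactor * boost
    f[isCtrlBound] <- cfg$controlEnrichment
    # mixture calibration on the overlap-effective +/-500 bp window
    Lmean <- cfg$fragmentLengthMean
    G <- cfg$effectiveGenomeSize
    cap <- stats::pnorm((500 + Lmean / 2) / cfg$peakSd) -
           stats::pnorm(-(500 + Lmean / 2) / cfg$peakSd)
    bgWinMass <- (1000 + Lmean) / G
    a <- (f - 1) * bgWinMass / cap
    mBg <- (1 - offtarget) / (1 + sum(a))
    w <- a * mBg
    chromLen <- cfg$chromLengths
    simLen <- sum(chromLen)
    pStoredBg <- mBg * simLen / G
    probs <- c(pStoredBg, w)
    set.seed(.deriveSeed(seed, 0L))
    counts <- as.vector(stats::rmultinom(1L, size = N,
                                         prob = c(probs, 1 - sum(probs))))
    nBg <- counts[1L]
    nPeak <- counts[1L + seq_along(w)]
    # background midpoints: uniform over instantiated chromosomes
    cum <- cumsum(as.numeric(chromLen))
    u <- stats::runif(nBg) * simLen
    chIdx <- findInterval(u, c(0, cum[-length(cum)]))
    bgChrom <- names(chromLen)[chIdx]
    bgMid <- u - c(0, cum)[chIdx]
    # peak midpoints
    anchors <- ifelse(truth$strand == "-", truth$end, truth$start)
    pkChrom <- rep(truth$chrom, nPeak)
    pkMid <- stats::rnorm(sum(nPeak), mean = rep(anchors, nPeak),
                          sd = cfg$peakSd)
    mid <- c(bgMid, pkMid)
    chrom <- c(bgChrom, pkChrom)
    len <- pmax(50, round(stats::rnorm(length(mid),
                                       cfg$fragmentLengthMean,
                                       cfg$fragmentLengthSd)))
    s1 <- pmax(1, round(mid - len / 2))
    e1 <- pmin(chromLen[chrom], s1 + len - 1)
    keep <- e1 >= s1 & e1 >= 1 & s1 <= chromLen[chrom]
    gr <- GRanges(chrom[keep], IRanges(as.integer(s1[keep]),
                                       as.integer(e1[keep])))
    gr <- gr[order(as.character(seqnames(gr)), start(gr))]
    truth$enrichmentFactor <- f
    truth$expectedWindowCount <- N * (mBg * bgWinMass + w * cap)
    list(fragments = new("FragmentSet", fragments = gr, librarySize = N,
                         source = paste0("simulated:", profile)),
         truth = truth, profile = profile, seed = seed)
}

#' Write the synthetic genome to standard files
#'
#' @param sim A [SyntheticGenome-class].
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths (FASTA, BED6 per region class,
#'   truth TSV).
#' @export
writeGenomeFiles <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(sim@sequence, fa)
    paths <- c(genome = fa)
    for (cl in c("tdna", "snorna", "mirna", "control")) {
        gr <- slot(sim, cl)
        if (length(gr)) {
            p <- file.path(dir, paste0(cl, ".bed"))
            writeRegionsBED(gr, p)
            paths[cl] <- p
        }
    }
    tp <- file.path(dir, "truth.tsv")
    utils::write.table(sim@truth, tp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["truth"] <- tp
    paths
}
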