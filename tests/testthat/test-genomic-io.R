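test_that("BED6 parsing maps fields under the 0-based half-open convention", {
    bed <- tempfile(fileext = ".bed")
    writeLines("chr1\t100\t200\ttRNA-X\t0\t+", bed)
    rg <- readRegions(bed, assembly = "hg38")
    expect_equal(as.character(seqnames(rg)), "chr1")
    expect_equal(start(rg), 101L)   # 0-based 100 -> 1-based 101
    expect_equal(end(rg), 200L)
    expect_equal(names(rg), "tRNA-X")
    expect_equal(as.character(strand(rg)), "+")
    expect_equal(assemblyLabel(rg), "hg38")
})

test_that("empty BED yields an empty region set without error", {
    bed <- tempfile(fileext = ".bed")
    file.create(bed)
    expect_length(readRegions(bed), 0L)
})

test_that("regions come out sorted by (chrom, start), names auto-filled", {
    set.seed(11)
    n <- 10L
    chrom <- sample(c("chr2", "chr1", "chr10"), n, replace = TRUE)
    s0 <- sample(1000:9999, n)
    tab <- data.frame(chrom, s0, s0 + 50L, paste0("g", seq_len(n)),
                      0L, sample(c("+", "-"), n, TRUE))
    bed <- tempfile(fileext = ".bed")
    writeLines(do.call(paste, c(tab, sep = "\t")), bed)
    rg <- readRegions(bed)
    # oracle: independent sort of the parsed tuples
    o <- order(tab[[1L]], tab[[2L]])
    expect_equal(as.character(seqnames(rg)), tab[[1L]][o])
    expect_equal(start(rg), tab[[2L]][o] + 1L)
    expect_equal(names(rg), tab[[4L]][o])
    # names generated when absent
    writeLines(paste("chr1", 10, 20, sep = "\t"), bed)
    expect_equal(names(readRegions(bed)), "chr1:10-20")
})

test_that("malformed BED lines are rejected with a line number", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t1\t10\tok", "chr1\txx\t20\tbad"), bed)
    expect_error(readRegions(bed), "line 2")
    writeLines(c("chr1\t100\t100\tzero"), bed)
    expect_error(readRegions(bed), "end <= start")
    writeLines(c("chr1\t1\t10\tdup", "chr1\t20\t30\tdup"), bed)
    expect_error(readRegions(bed), "duplicate")
})

test_that("BED6 round-trip is byte-identical for canonical files", {
    lines <- c("chr1\t100\t200\tgeneA\t0\t+",
               "chr1\t500\t600\tgeneB\t0\t-",
               "chr2\t10\t90\tgeneC\t0\t.")
    bed <- tempfile(fileext = ".bed")
    writeLines(lines, bed)
    out <- tempfile(fileext = ".bed")
    writeRegionsBED(readRegions(bed), out)
    expect_identical(readLines(out), lines)
})

test_that("UCSC-style TSV tables are read like BED", {
    tsv <- tempfile(fileext = ".tsv")
    writeLines(c("#chrom\tchromStart\tchromEnd\tname\tstrand",
                 "chr1\t100\t175\ttRNA-Y\t-"), tsv)
    rg <- readRegions(tsv, format = "tsv")
    expect_equal(start(rg), 101L)
    expect_equal(as.character(strand(rg)), "-")
    expect_equal(names(rg), "tRNA-Y")
})

test_that("paired reads collapse to the template span", {
    sam <- tempfile(fileext = ".sam")
    # mates at [101,150] (+) and [221,270] (-): template [101,270]
    writeSAM(data.frame(qname = c("p1", "p1"), flag = c(99L, 147L),
                        rname = "chr1", pos = c(101L, 221L),
                        cigar = "50M"),
             c(chr1 = 100000L), sam)
    fs <- readFragments(sam)
    fr <- fragments(fs)
    expect_equal(length(fr), 1L)
    expect_equal(start(fr), 101L)
    expect_equal(end(fr), 270L)
    expect_equal(librarySize(fs), 1)
})

test_that("single-end reads extend 3' to the requested fragment size", {
    sam <- tempfile(fileext = ".sam")
    writeSAM(data.frame(qname = c("plus", "minus"), flag = c(0L, 16L),
                        rname = "chr1", pos = c(101L, 1001L),
                        cigar = "36M"),
             c(chr1 = 100000L), sam)
    fr <- fragments(readFragments(sam, singleEndExtension = 200L))
    # + read [101,136] -> [101,300]; - read [1001,1036] -> [837,1036]
    expect_equal(start(fr), c(101L, 837L))
    expect_equal(end(fr), c(300L, 1036L))
})

test_that("template count on a mixed fixture matches the hand count and is
           order-invariant", {
    set.seed(3)
    npair <- 18L; nsgl <- 14L   # 50 records total
    recs <- rbind(
        do.call(rbind, lapply(seq_len(npair), function(i)
            data.frame(qname = paste0("p", i), flag = c(99L, 147L),
                       rname = sample(c("chr1", "chr2"), 1L),
                       pos = sort(sample(1000:50000, 2L)),
                       cigar = "36M"))),
        data.frame(qname = paste0("s", seq_len(nsgl)),
                   flag = sample(c(0L, 16L), nsgl, TRUE),
                   rname = sample(c("chr1", "chr2"), nsgl, TRUE),
                   pos = sample(1000:50000, nsgl), cigar = "36M"))
    expect_equal(nrow(recs), 50L)
    sam <- tempfile(fileext = ".sam")
    writeSAM(recs, c(chr1 = 100000L, chr2 = 100000L), sam)
    fs <- readFragments(sam)
    expect_equal(librarySize(fs), npair + nsgl)   # manual enumeration
    # shuffle record order: same fragments
    sam2 <- tempfile(fileext = ".sam")
    writeSAM(recs[sample(nrow(recs)), ], c(chr1 = 100000L, chr2 = 100000L),
             sam2)
    fs2 <- readFragments(sam2)
    expect_equal(librarySize(fs2), librarySize(fs))
    expect_identical(sort(fragments(fs)), sort(fragments(fs2)))
    # no fragment with end <= start
    expect_true(all(end(fragments(fs)) >= start(fragments(fs))))
})

test_that("a paired-flagged read without its mate degrades to single-end
           with a warning", {
    sam <- tempfile(fileext = ".sam")
    writeSAM(data.frame(qname = "orphan", flag = 99L, rname = "chr1",
                        pos = 101L, cigar = "36M"),
             c(chr1 = 100000L), sam)
    expect_warning(fs <- readFragments(sam), "mate")
    expect_equal(end(fragments(fs)), 300L)
})

test_that("BED fragments are taken verbatim and empty input is valid", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t100\t300", "chr1\t500\t700"), bed)
    fs <- readFragments(bed)
    expect_equal(start(fragments(fs)), c(101L, 501L))
    expect_equal(librarySize(fs), 2)
    file.create(bed2 <- tempfile(fileext = ".bed"))
    expect_equal(librarySize(readFragments(bed2)), 0)
})

test_that("sequence extraction slices, flanks and clips correctly", {
    genome <- Biostrings::DNAStringSet(c(chrT = "AACGTACG"))
    rg <- gr6("chrT", 4, 7, "x")   # 0-based [3,7) of AACGTACG
    expect_equal(unname(extractSequence(genome, rg)), "GTAC")
    # flank beyond bounds: whole chromosome, no padding
    expect_equal(unname(extractSequence(genome, rg, flank = 100L)),
                 "AACGTACG")
    expect_error(extractSequence(genome, gr6("chrZ", 1, 2, "y")),
                 "not in genome")
    # flanked length by coordinate arithmetic on a longer chromosome
    genome2 <- Biostrings::DNAStringSet(c(chrL = randSeq(50000)))
    rg2 <- gr6("chrL", 30001, 30080, "g")
    up <- min(20000, 30000); down <- min(20000, 50000 - 30080)
    expect_equal(unname(nchar(extractSequence(genome2, rg2,
                                              flank = 20000L))),
                 80 + up + down)
})

test_that("bedGraph round-trips a step function", {
    track <- list(chrom = "chr1", start0 = 1000L,
                  values = c(0, 0, 1, 1, 1, 2.5, 2.5, 0, 3, 0))
    p <- tempfile(fileext = ".bedGraph")
    writeBedGraph(track, p)
    back <- readBedGraph(p)
    expect_equal(back$chrom, "chr1")
    expect_equal(back$start0, 1000L)
    expect_equal(back$values, track$values)
})

test_that("QTable TSV round-trips values and coordinates", {
    fs <- fragSet("chr1", c(100, 900), c(300, 1100), librarySize = 1e6)
    rg <- gr6("chr1", c(1001, 5001), c(1080, 5080), c("a", "b"), "+")
    q <- quantifyRegions(fs, rg)
    p <- tempfile(fileext = ".tsv")
    writeQTable(q, p)
    back <- readQTable(p)
    expect_equal(qTable(back)$Q, qTable(q)$Q)
    expect_equal(qTable(back)$start, qTable(q)$start)
})
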