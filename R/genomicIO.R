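#' Read a region set from BED6 or a UCSC-style TSV table
#'
#' Parses gene annotation intervals into a named, sorted \code{GRanges}.
#' Coordinates on disk follow the 0-based half-open BED convention; the
#' returned \code{GRanges} is 1-based as usual. Regions lacking a name get
#' \code{chrom:start-end}. Output is sorted by (chromosome, start) and names
#' must be unique.
#'
#' @param path Path to the file.
#' @param format \code{"bed"} (>= 3 columns, tab-separated) or \code{"tsv"}
#'   (header with columns chrom/chromStart/chromEnd or chrom/start/end, plus
#'   optional name and strand, UCSC Table Browser style).
#' @param assembly Optional assembly label to attach (e.g. \code{"hg38"}).
#' @return A named, sorted \code{GRanges} with \code{metadata()$assembly}.
#'
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\ttRNA-X\t0\t+", bed)
#' readRegions(bed, assembly = "toy")
#' @export
readRegions <- function(path, format = c("bed", "tsv"), assembly = NA) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    if (format == "bed") {
        lines <- readLines(path)
        lines <- lines[!grepl("^(#|track|browser)", lines)]
        lines <- lines[nzchar(trimws(lines))]
        if (length(lines) == 0L)
            return(.makeRegions(character(), integer(), integer(),
                                character(), character(), assembly))
        fields <- strsplit(lines, "\t", fixed = TRUE)
        nf <- lengths(fields)
        if (any(nf < 3L))
            stop("malformed BED line ", which(nf < 3L)[1L],
                 ": fewer than 3 columns", call. = FALSE)
        chrom <- vapply(fields, `[[`, "", 1L)
        start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
        end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
        badnum <- which(is.na(start0) | is.na(end))
        if (length(badnum))
            stop("malformed BED line ", badnum[1L],
                 ": non-numeric coordinates", call. = FALSE)
        name <- ifelse(nf >= 4L,
                       vapply(fields, function(f)
                           if (length(f) >= 4L) f[[4L]] else "", ""),
                       "")
        strand <- ifelse(nf >= 6L,
                         vapply(fields, function(f)
                             if (length(f) >= 6L) f[[6L]] else "*", ""),
                         "*")
    } else {
        tab <- utils::read.delim(path, check.names = FALSE,
                                 stringsAsFactors = FALSE)
        names(tab) <- sub("^#", "", names(tab))
        pick <- function(...) {
            for (cand in c(...)) if (cand %in% names(tab)) return(tab[[cand]])
            NULL
        }
        chrom <- pick("chrom", "chr", "seqnames")
        start0 <- pick("chromStart", "start", "txStart")
        end <- pick("chromEnd", "end", "txEnd")
        if (is.null(chrom) || is.null(start0) || is.null(end))
            stop("TSV table must have chrom/start/end columns", call. = FALSE)
        name <- pick("name", "gene")
        if (is.null(name)) name <- rep("", nrow(tab))
        strand <- pick("strand")
        if (is.null(strand)) strand <- rep("*", nrow(tab))
        start0 <- as.integer(start0); end <- as.integer(end)
    }
    empty <- !nzchar(name) | name == "."
    name[empty] <- paste0(chrom[empty], ":", start0[empty], "-", end[empty])
    .makeRegions(chrom, start0, end, name, strand, assembly)
}

#' Write a region set as BED6
#'
#' Inverse of [readRegions()]: writes 0-based half-open coordinates, name,
#' a zero score, and strand as six tab-separated columns. Reading the file
#' back reproduces the region set exactly.
#'
#' @param regions Named \code{GRanges}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeRegionsBED <- function(regions, path) {
    validateRegions(regions)
    s <- as.character(strand(regions))
    s[s == "*"] <- "."
    lines <- paste(as.character(seqnames(regions)), start(regions) - 1L,
                   end(regions), names(regions), 0L, s, sep = "\t")
    writeLines(lines, path)
    invisible(path)
}

#' Read a sequencing library as DNA fragments
#'
#' Builds a [FragmentSet-class] from aligned reads. Properly mated pairs are
#' collapsed to one fragment spanning the whole template; single-end reads
#' (and reads whose mate is missing, with a warning) are extended to
#' \code{singleEndExtension} bp in the 3' direction of their strand. BED
#' intervals are taken verbatim as fragments. Unmapped, secondary and
#' supplementary records are skipped.
#'
#' @param path SAM, BAM or BED file. SAM is converted on the fly.
#' @param format \code{"auto"} (by extension), \code{"bam"}, \code{"sam"} or
#'   \code{"bed"}.
#' @param singleEndExtension Extension length in bp for single-end reads
#'   (default 200, a typical ChIP fragment size).
#' @return A \code{FragmentSet}; \code{librarySize} is the number of
#'   resulting fragments.
#' @export
readFragments <- function(path, format = c("auto", "bam", "sam", "bed"),
                          singleEndExtension = 200L) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, bam = "bam", sam = "sam", bed = "bed",
                         stop("cannot infer format from extension '", ext,
                              "'", call. = FALSE))
    }
    if (format == "bed") {
        lines <- readLines(path)
        lines <- lines[nzchar(trimws(lines)) &
                       !grepl("^(#|track|browser)", lines)]
        if (length(lines) == 0L) {
            gr <- GRanges()
        } else {
            fields <- strsplit(lines, "\t", fixed = TRUE)
            if (any(lengths(fields) < 3L))
                stop("malformed BED line ",
                     which(lengths(fields) < 3L)[1L], call. = FALSE)
            chrom <- vapply(fields, `[[`, "", 1L)
            s0 <- as.integer(vapply(fields, `[[`, "", 2L))
            e <- as.integer(vapply(fields, `[[`, "", 3L))
            if (any(e <= s0))
                stop("fragment with end <= start at line ",
                     which(e <= s0)[1L], call. = FALSE)
            gr <- GRanges(chrom, IRanges(s0 + 1L, e))
        }
        return(new("FragmentSet", fragments = gr,
                   librarySize = as.numeric(length(gr)), source = "bed"))
    }
    bam <- path
    if (format == "sam")
        bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                                indexDestination = FALSE)
    bamflag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                      isSecondaryAlignment = FALSE,
                                      isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(flag = bamflag, what = "flag")
    aln <- GenomicAlignments::readGAlignments(bam, use.names = TRUE,
                                              param = param)
    gr <- GRanges(aln)
    frags <- GRanges()
    if (length(gr)) {
        qn <- names(gr)
        cnt <- table(qn)
        pairedQn <- names(cnt)[cnt == 2L]
        isPairMember <- qn %in% pairedQn
        singles <- gr[!isPairMember]
        mates <- gr[isPairMember]
        tmpl <- GRanges()
        if (length(mates)) {
            spl <- S4Vectors::split(mates, names(mates))
            samechrom <- vapply(spl, function(p)
                length(unique(as.character(seqnames(p)))) == 1L, TRUE)
            if (any(samechrom))
                tmpl <- unlist(range(spl[samechrom], ignore.strand = TRUE),
                               use.names = FALSE)
            # cross-chromosome "pairs" degrade to single-end
            if (any(!samechrom))
                singles <- c(singles, unlist(spl[!samechrom],
                                             use.names = FALSE))
        }
        if (any(cnt > 2L))
            warning(sum(cnt > 2L), " read name(s) with >2 alignments; ",
                    "each alignment treated as single-end")
        if (length(singles)) {
            orphan <- bitwAnd(S4Vectors::mcols(singles)$flag, 1L) > 0L
            if (any(orphan, na.rm = TRUE))
                warning(sum(orphan, na.rm = TRUE),
                        " paired-flagged read(s) without a mapped mate; ",
                        "treated as single-end and extended")
            neg <- as.character(strand(singles)) == "-"
            ext <- as.integer(singleEndExtension)
            newStart <- ifelse(neg, pmax(end(singles) - ext + 1L, 1L),
                               start(singles))
            newEnd <- ifelse(neg, end(singles), start(singles) + ext - 1L)
            sglx <- GRanges(seqnames(singles), IRanges(newStart, newEnd))
            frags <- c(granges(tmpl), granges(sglx))
        } else {
            frags <- granges(tmpl)
        }
        names(frags) <- NULL
        strand(frags) <- "*"
        S4Vectors::mcols(frags) <- NULL
    }
    new("FragmentSet", fragments = frags,
        librarySize = as.numeric(length(frags)),
        source = paste0(format, ";extend=", singleEndExtension))
}

#' Write fragments as a BED3 file
#'
#' @param fragset A \code{FragmentSet}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeFragmentsBED <- function(fragset, path) {
    fr <- fragments(fragset)
    writeLines(paste(as.character(seqnames(fr)), start(fr) - 1L, end(fr),
                     sep = "\t"), path)
    invisible(path)
}

#' Extract a (flanked) genomic sequence
#'
#' Returns the forward-strand, upper-cased sequence of
#' \code{[start - flank, end + flank)} for one region, clipped to chromosome
#' bounds (no padding).
#'
#' @param genome A \code{DNAStringSet} (e.g. from
#'   \code{Biostrings::readDNAStringSet}) or path to a FASTA file.
#' @param region A length-1 named \code{GRanges} (or a \code{GRanges}; all
#'   entries are extracted).
#' @param flank Flank in bp added on both sides (default 0).
#' @return A character vector of sequences, named by region.
#' @export
extractSequence <- function(genome, region, flank = 0L) {
    if (is.character(genome) && length(genome) == 1L)
        genome <- Biostrings::readDNAStringSet(genome)
    # FASTA headers may carry descriptions; keep the first word
    names(genome) <- sub("\\s.*", "", names(genome))
    chrom <- as.character(seqnames(region))
    missing <- setdiff(unique(chrom), names(genome))
    if (length(missing))
        stop("chromosome(s) not in genome: ",
             paste(missing, collapse = ", "), call. = FALSE)
    out <- character(length(region))
    for (i in seq_along(region)) {
        len <- length(genome[[chrom[i]]])
        s <- max(1L, start(region)[i] - flank)
        e <- min(len, end(region)[i] + flank)
        out[i] <- toupper(as.character(
            Biostrings::subseq(genome[[chrom[i]]], s, e)))
    }
    names(out) <- names(region)
    out
}

#' Write a per-base coverage track as bedGraph
#'
#' Adjacent positions with equal values are merged into one interval;
#' zero-valued runs are written too so a round-trip reproduces the step
#' function over the covered range.
#'
#' @param track Named list as produced by [coverageTrack()]: \code{chrom},
#'   \code{start0} (0-based start of the window), \code{values} (per-base).
#' @param path Output path.
#' @param dropZero Omit zero-valued intervals (conventional bedGraph;
#'   default \code{FALSE}).
#' @return The path, invisibly.
#' @export
writeBedGraph <- function(track, path, dropZero = FALSE) {
    v <- track$values
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- rep(TRUE, length(r$values))
    if (dropZero) keep <- r$values != 0
    lines <- paste(track$chrom, track$start0 + starts[keep],
                   track$start0 + ends[keep],
                   format(r$values[keep], trim = TRUE, scientific = FALSE),
                   sep = "\t")
    writeLines(lines, path)
    invisible(path)
}

#' Read a bedGraph file back into a per-base step function
#'
#' @param path bedGraph path.
#' @return A list with \code{chrom}, \code{start0} and per-base
#'   \code{values} spanning the covered range.
#' @export
readBedGraph <- function(path) {
    tab <- utils::read.delim(path, header = FALSE,
                             col.names = c("chrom", "start", "end", "value"))
    if (length(unique(tab$chrom)) > 1L)
        stop("multi-chromosome bedGraph not supported here", call. = FALSE)
    lo <- min(tab$start); hi <- max(tab$end)
    v <- numeric(hi - lo)
    for (i in seq_len(nrow(tab)))
        v[(tab$start[i] - lo + 1L):(tab$end[i] - lo)] <- tab$value[i]
    list(chrom = tab$chrom[1L], start0 = lo, values = v)
}

#' Write a QTable as TSV
#'
#' Columns: name, chrom, start, end, strand, raw_count, Q. Coordinates are
#' written 0-based half-open to match the BED inputs.
#'
#' @param q A \code{QTable}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeQTable <- function(q, path) {
    tab <- qTable(q)
    out <- data.frame(name = tab$name, chrom = tab$chrom,
                      start = tab$start - 1L, end = tab$end,
                      strand = tab$strand, raw_count = tab$raw, Q = tab$Q)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a QTable written by [writeQTable()]
#'
#' @param path TSV path.
#' @param config Optional \code{QuantConfig} to attach.
#' @param librarySize Library size to attach (default \code{NA}).
#' @return A \code{QTable}.
#' @export
readQTable <- function(path, config = quantConfig(), librarySize = NA_real_) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    new("QTable",
        table = data.frame(name = tab$name, chrom = tab$chrom,
                           start = tab$start + 1L, end = tab$end,
                           strand = tab$strand, raw = tab$raw_count,
                           Q = tab$Q),
        config = config, librarySize = librarySize)
}
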