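#' Create a quantification configuration
#'
#' Defaults mirror the standard windowed-occupancy setup for Pol III genes:
#' a +/-500 bp window around the strand-aware gene start, normalized to
#' fragments per million, without per-kb length normalization.
#'
#' @param upstream,downstream Window extents in bp (defaults 500/500).
#' @param anchor \code{"gene_start"} (5' end, default) or
#'   \code{"gene_centre"}.
#' @param rpm Normalize counts to fragments per million (default
#'   \code{TRUE}).
#' @param perKb Additionally normalize to a 1000 bp window (default
#'   \code{FALSE}).
#' @return A [QuantConfig-class].
#' @examples
#' quantConfig()                  # the default +/-500 bp RPM setup
#' quantConfig(2000, 2000)        # +/-2 kb
#' @export
quantConfig <- function(upstream = 500L, downstream = 500L,
                        anchor = c("gene_start", "gene_centre"),
                        rpm = TRUE, perKb = FALSE) {
    anchor <- match.arg(anchor)
    new("QuantConfig", upstream = as.integer(upstream),
        downstream = as.integer(downstream), anchor = anchor,
        rpm = rpm, perKb = perKb)
}

#' Quantify ChIP occupancy at regions ("Q-values")
#'
#' For each region, counts the fragments of the library that overlap (by at
#' least 1 bp) a window placed around the region's anchor, and normalizes:
#' Q = count x 10^6 / librarySize when RPM normalization is on, further
#' divided by (window length / 1000) when per-kb normalization is on. The
#' window covers \code{upstream} bp in the 5' direction of the anchor and
#' \code{downstream} bp in the 3' direction (strand-aware; unstranded
#' regions are treated as plus strand).
#'
#' @param fragset A [FragmentSet-class].
#' @param regions Non-empty named \code{GRanges}.
#' @param config A [QuantConfig-class] (default [quantConfig()]).
#' @return A [QTable-class] with one row per region, in region order.
#' @examples
#' fr <- new("FragmentSet",
#'           fragments = GenomicRanges::GRanges("chr1",
#'                           IRanges::IRanges(c(900, 950, 2000),
#'                                            c(1100, 1150, 2200))),
#'           librarySize = 1e6, source = "example")
#' rg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1075),
#'                              strand = "+")
#' names(rg) <- "tRNA-X"
#' qValues(quantifyRegions(fr, rg))   # 2 fragments in +/-500 bp -> Q = 2
#' @export
quantifyRegions <- function(fragset, regions, config = quantConfig()) {
    validateRegions(regions)
    if (length(regions) == 0L)
        stop("empty region set", call. = FALSE)
    validObject(config)
    if (config@rpm && librarySize(fragset) <= 0)
        stop("librarySize must be > 0 for RPM normalization", call. = FALSE)
    win <- .quantWindows(regions, config)
    raw <- GenomicRanges::countOverlaps(win, fragments(fragset),
                                        ignore.strand = TRUE)
    q <- as.numeric(raw)
    if (config@rpm)
        q <- q * 1e6 / librarySize(fragset)
    if (config@perKb)
        q <- q / ((config@upstream + config@downstream) / 1000)
    new("QTable",
        table = data.frame(name = names(regions),
                           chrom = as.character(seqnames(regions)),
                           start = start(regions), end = end(regions),
                           strand = as.character(strand(regions)),
                           raw = as.integer(raw), Q = q,
                           stringsAsFactors = FALSE, row.names = NULL),
        config = config, librarySize = librarySize(fragset))
}

#' Rank regions by increasing occupancy
#'
#' Stable ascending sort on Q; ties broken by (chromosome, start).
#' Idempotent on already-sorted tables.
#'
#' @param q A [QTable-class].
#' @return The same \code{QTable} with rows reordered.
#' @export
rankRegions <- function(q) {
    tab <- qTable(q)
    o <- order(tab$Q, tab$chrom, tab$start)
    q@table <- tab[o, , drop = FALSE]
    rownames(q@table) <- NULL
    q
}

#' Select the top-N regions by occupancy
#'
#' Returns the \code{n} regions with the largest Q values as a region
#' \code{GRanges}. A tie at the selection boundary is resolved by
#' (chromosome, start), lowest first, so the result is deterministic.
#'
#' @param q A [QTable-class].
#' @param n Number of regions, \code{1 <= n <= nrow}; 50 is the
#'   conventional choice for downstream category analysis.
#' @return Named \code{GRanges} of the selected regions, ordered by
#'   decreasing Q.
#' @export
topRegions <- function(q, n = 50L) {
    tab <- qTable(q)
    if (n < 1L || n > nrow(tab))
        stop("n must be between 1 and ", nrow(tab), call. = FALSE)
    o <- order(-tab$Q, tab$chrom, tab$start)
    sel <- tab[o[seq_len(n)], , drop = FALSE]
    gr <- GRanges(sel$chrom, IRanges(sel$start, sel$end),
                  strand = sel$strand)
    names(gr) <- sel$name
    gr$Q <- sel$Q
    gr
}

#' Occupancy and binned signal at a single named locus
#'
#' Applies the same counting contract as [quantifyRegions()] to one locus,
#' with the window anchored either at the locus 5' start (mode
#' \code{"upstream"}, e.g. a +/-2 kb window around a GREB1-like start) or
#' at the locus centre (mode \code{"centred"}, e.g. +/-2.5 kb around a
#' short gene body). Also returns the per-bin coverage for plotting.
#'
#' @param fragset A [FragmentSet-class].
#' @param locus A length-1 named \code{GRanges}.
#' @param flank Half-window in bp.
#' @param mode \code{"upstream"} (anchor at gene start) or \code{"centred"}.
#' @param binSize Bin width for the returned track (default 50 bp).
#' @return A list: \code{Q} (fragments per million overlapping the window),
#'   \code{raw}, \code{window} (\code{GRanges}), \code{track} (data.frame
#'   of bin offset midpoints and per-bin RPM).
#' @export
locusSignal <- function(fragset, locus, flank = 2000L,
                        mode = c("upstream", "centred"), binSize = 50L) {
    mode <- match.arg(mode)
    if (length(locus) != 1L)
        stop("'locus' must be a single region", call. = FALSE)
    anchor <- if (mode == "upstream") "gene_start" else "gene_centre"
    cfg <- quantConfig(flank, flank, anchor = anchor, rpm = TRUE)
    qt <- quantifyRegions(fragset, locus, cfg)
    win <- .quantWindows(locus, cfg)
    nbin <- as.integer(2L * flank %/% binSize)
    edges <- start(win) + (0:nbin) * as.integer(binSize)
    bins <- GRanges(seqnames(win),
                    IRanges(edges[-length(edges)], edges[-1L] - 1L))
    cnt <- GenomicRanges::countOverlaps(bins, fragments(fragset),
                                        ignore.strand = TRUE)
    a <- .anchorPos(locus, anchor)
    mid <- (start(bins) + end(bins)) / 2 - a
    list(Q = unname(qValues(qt)), raw = unname(rawCounts(qt)),
         window = win,
         track = data.frame(offset = mid,
                            rpm = cnt * 1e6 / librarySize(fragset)))
}
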