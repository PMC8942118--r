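#' Build a regions-by-bins signal matrix for ranked heatmaps
#'
#' Each cell holds the RPM-normalized number of fragments overlapping that
#' bin's genomic interval. Bins tile a +/-\code{flank} window around the
#' region anchor (gene centre by default, matching heatmap and metagene
#' conventions for short Pol III genes). Rows follow the order of the
#' supplied occupancy table, so ranking the table by increasing Q yields
#' the classic ranked heatmap layout. When \code{orientByStrand} is on,
#' minus-strand rows are reversed so upstream is always on the left.
#'
#' @param fragset A [FragmentSet-class].
#' @param regions Named \code{GRanges}; all must appear in \code{order}.
#' @param order A [QTable-class] defining row order (e.g. from
#'   [rankRegions()]), or \code{NULL} to keep region order.
#' @param flank Half-window in bp (default 10000).
#' @param binSize Bin width in bp (default 50); must divide \code{flank}.
#' @param anchor \code{"gene_centre"} (default) or \code{"gene_start"}.
#' @param orientByStrand Reverse minus-strand rows (default \code{FALSE}
#'   for centre anchoring, \code{TRUE} for start anchoring).
#' @return A [SignalMatrix-class].
#' @export
signalMatrix <- function(fragset, regions, order = NULL, flank = 10000L,
                         binSize = 50L,
                         anchor = c("gene_centre", "gene_start"),
                         orientByStrand = (anchor == "gene_start")) {
    anchor <- match.arg(anchor)
    validateRegions(regions)
    if (length(regions) == 0L)
        stop("empty region set", call. = FALSE)
    flank <- as.integer(flank); binSize <- as.integer(binSize)
    if (flank %% binSize != 0L)
        stop("flank must be divisible by binSize", call. = FALSE)
    if (!is.null(order)) {
        nm <- qTable(order)$name
        if (!all(names(regions) %in% nm))
            stop("'order' does not cover all regions", call. = FALSE)
        regions <- regions[nm[nm %in% names(regions)]]
    }
    nbin <- 2L * flank %/% binSize
    a <- .anchorPos(regions, anchor)
    off <- seq(-flank, flank - binSize, by = binSize)
    # all bins of all regions in one GRanges, region-major
    binStart <- rep(a, each = nbin) + rep(off, length(regions))
    binEnd <- binStart + binSize - 1L
    clipped <- binEnd < 1L
    if (any(clipped))
        message(sum(clipped), " bin(s) outside chromosome bounds set to 0")
    bins <- GRanges(rep(seqnames(regions), each = nbin),
                    IRanges(pmax(binStart, 1L), pmax(binEnd, 1L)))
    cnt <- GenomicRanges::countOverlaps(bins, fragments(fragset),
                                        ignore.strand = TRUE)
    cnt[clipped] <- 0L
    vals <- matrix(cnt * 1e6 / librarySize(fragset),
                   nrow = length(regions), ncol = nbin, byrow = TRUE,
                   dimnames = list(names(regions), NULL))
    if (isTRUE(orientByStrand)) {
        neg <- as.character(strand(regions)) == "-"
        if (any(neg))
            vals[neg, ] <- vals[neg, rev(seq_len(nbin)), drop = FALSE]
    }
    new("SignalMatrix", values = vals, binMid = off + binSize / 2,
        anchor = anchor, flank = flank, binSize = binSize)
}

#' Average (metagene) signal profile
#'
#' Column means of one or more signal matrices sharing a common bin axis —
#' the average signal intensity profile across all regions. Passing several
#' matrices (e.g. two replicates) returns one profile per matrix for
#' overlay plotting.
#'
#' @param ... One or more [SignalMatrix-class] objects (or a single list of
#'   them).
#' @return A data.frame with column \code{offset} (bin midpoints) and one
#'   mean-signal column per input matrix, in input order.
#' @export
averageProfile <- function(...) {
    mats <- list(...)
    if (length(mats) == 1L && is.list(mats[[1L]]) &&
        !is(mats[[1L]], "SignalMatrix"))
        mats <- mats[[1L]]
    if (length(mats) == 0L)
        stop("no signal matrices supplied", call. = FALSE)
    if (any(!vapply(mats, is, TRUE, "SignalMatrix")))
        stop("all inputs must be SignalMatrix objects", call. = FALSE)
    if (any(vapply(mats, function(m) nrow(m@values), 1L) == 0L))
        stop("empty signal matrix", call. = FALSE)
    ref <- binOffsets(mats[[1L]])
    for (m in mats[-1L])
        if (!isTRUE(all.equal(binOffsets(m), ref)))
            stop("bin axes differ between matrices", call. = FALSE)
    out <- data.frame(offset = ref)
    nm <- names(mats)
    if (is.null(nm)) nm <- rep("", length(mats))
    for (i in seq_along(mats)) {
        cn <- if (nzchar(nm[i])) nm[i] else paste0("mean", i)
        out[[cn]] <- colMeans(signalValues(mats[[i]]))
    }
    out
}

#' Per-base coverage track around a locus ("filltrack")
#'
#' RPM-normalized per-base fragment coverage over
#' \code{[start - flank, end + flank)}, clipped at the chromosome start.
#' Suitable for bedGraph export via [writeBedGraph()].
#'
#' @param fragset A [FragmentSet-class].
#' @param locus A length-1 \code{GRanges}.
#' @param flank Flank in bp on both sides.
#' @return A list: \code{chrom}, \code{start0} (0-based window start) and
#'   \code{values} (per-base RPM).
#' @export
coverageTrack <- function(fragset, locus, flank = 0L) {
    if (length(locus) != 1L)
        stop("'locus' must be a single region", call. = FALSE)
    ws <- max(1L, start(locus) - as.integer(flank))
    we <- end(locus) + as.integer(flank)
    fr <- fragments(fragset)
    fr <- fr[as.character(seqnames(fr)) == as.character(seqnames(locus))]
    v <- numeric(we - ws + 1L)
    if (length(fr)) {
        cov <- GenomicRanges::coverage(fr)[[as.character(seqnames(locus))]]
        covlen <- length(cov)
        hi <- min(we, covlen)
        if (hi >= ws)
            v[seq_len(hi - ws + 1L)] <- as.numeric(
                S4Vectors::window(cov, ws, hi))
    }
    list(chrom = as.character(seqnames(locus)), start0 = ws - 1L,
         values = v * 1e6 / librarySize(fragset))
}
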