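#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors metadata metadata<-
NULL

# Internal: construct a sorted, validated region GRanges from parsed fields.
# starts are 0-based half-open (BED convention); GRanges stores 1-based.
.makeRegions <- function(chrom, start0, end, name, strand, assembly = NA) {
    bad <- which(end <= start0)
    if (length(bad))
        stop("invalid interval (end <= start) for region '", name[bad[1L]],
             "'", call. = FALSE)
    if (anyDuplicated(name))
        stop("duplicate region name(s): ",
             paste(unique(name[duplicated(name)])[1:3], collapse = ", "),
             call. = FALSE)
    strand[!strand %in% c("+", "-")] <- "*"
    gr <- GRanges(chrom, IRanges(start0 + 1L, end), strand = strand)
    names(gr) <- name
    gr <- gr[order(as.character(seqnames(gr)), start(gr))]
    metadata(gr)$assembly <- assembly
    gr
}

#' Validate a region set
#'
#' Checks the invariants expected of a region \code{GRanges} throughout the
#' package: unique non-empty names, positive widths, and sorting by
#' (chromosome, start). Called internally by every consumer of regions.
#'
#' @param regions A named \code{GRanges}.
#' @param require.sorted Logical, also require (chrom, start) order.
#' @return Invisibly \code{TRUE}; stops with an informative error otherwise.
#' @export
validateRegions <- function(regions, require.sorted = FALSE) {
    if (!is(regions, "GRanges"))
        stop("regions must be a GRanges", call. = FALSE)
    if (length(regions) == 0L) return(invisible(TRUE))
    nm <- names(regions)
    if (is.null(nm) || any(nm == "") || anyNA(nm))
        stop("all regions must be named", call. = FALSE)
    if (anyDuplicated(nm))
        stop("region names must be unique", call. = FALSE)
    if (require.sorted) {
        o <- order(as.character(seqnames(regions)), start(regions))
        if (!identical(o, seq_along(regions)))
            stop("regions must be sorted by (chrom, start)", call. = FALSE)
    }
    invisible(TRUE)
}

#' Assembly label of a region set
#'
#' @param regions A \code{GRanges} produced by [readRegions()] or the
#'   simulator.
#' @return The assembly label (character scalar, possibly \code{NA}).
#' @export
assemblyLabel <- function(regions) {
    a <- metadata(regions)$assembly
    if (is.null(a)) NA_character_ else a
}

# Internal: strand-aware anchor coordinate (1-based) for each region.
# gene_start = 5' end (+/* -> start; - -> end); gene_centre = midpoint.
.anchorPos <- function(regions, anchor) {
    s <- as.character(strand(regions))
    if (anchor == "gene_start") {
        ifelse(s == "-", end(regions), start(regions))
    } else {
        floor((start(regions) + end(regions)) / 2)
    }
}

# Internal: strand-aware quantification windows as GRanges (1-based,
# clipped at chromosome start). Window covers `up` bp 5' of the anchor and
# `down` bp 3' of it: in 0-based terms [anchor - up, anchor + down).
.quantWindows <- function(regions, config) {
    a <- .anchorPos(regions, config@anchor)
    s <- as.character(strand(regions))
    neg <- s == "-"
    up <- config@upstream
    down <- config@downstream
    # + strand (and unstranded): [a - up, a + down); - strand mirrored
    ws <- ifelse(neg, a - down + 1L, a - up)
    we <- ifelse(neg, a + up, a + down - 1L)
    ws <- pmax(ws, 1L)
    gr <- GRanges(seqnames(regions), IRanges(ws, we))
    names(gr) <- names(regions)
    gr
}

# Internal: deterministic seed derivation, kept below 2^31.
.deriveSeed <- function(seed, k) {
    (as.numeric(seed) * 1000 + k) %% 2147483647
}
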