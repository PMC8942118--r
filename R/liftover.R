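#' Read a UCSC chain file as a ChainMap
#'
#' @param path Path to a UCSC chain file.
#' @param from Source assembly label (must match the regions to be lifted).
#' @param to Target assembly label.
#' @return A [ChainMap-class].
#' @export
readChain <- function(path, from, to) {
    if (!file.exists(path))
        stop("chain file not found: ", path, call. = FALSE)
    new("ChainMap", chain = rtracklayer::import.chain(path),
        from = from, to = to)
}

#' Remap regions between assemblies through an alignment chain
#'
#' Applies a strict full-length mapping rule: a region is considered
#' successfully remapped only if every one of its bases maps through the
#' chain to a single contiguous target interval on one chromosome and one
#' strand. Regions that straddle chain gaps, map partially, or map to
#' multiple pieces are reported as unmapped.
#'
#' @param regions Named \code{GRanges} with an assembly label matching
#'   \code{chain@from} (set by [readRegions()] or the simulator).
#' @param chain A [ChainMap-class].
#' @return A list:
#' \describe{
#'   \item{mapped}{Named \code{GRanges} of remapped regions (target
#'     assembly label attached), in (chrom, start) order.}
#'   \item{unmapped}{Character vector of region names that failed.}
#'   \item{remapRate}{mapped / (mapped + unmapped).}
#' }
#' @export
liftoverRegions <- function(regions, chain) {
    validateRegions(regions)
    if (!is(chain, "ChainMap"))
        stop("'chain' must be a ChainMap", call. = FALSE)
    src <- assemblyLabel(regions)
    if (!is.na(src) && !identical(src, chain@from))
        stop("assembly mismatch: regions are '", src,
             "' but chain maps from '", chain@from, "'", call. = FALSE)
    if (length(regions) == 0L)
        return(list(mapped = regions, unmapped = character(),
                    remapRate = NaN))
    hits <- rtracklayer::liftOver(regions, chain@chain)
    w <- width(regions)
    ok <- logical(length(regions))
    out <- vector("list", length(regions))
    for (i in seq_along(regions)) {
        h <- hits[[i]]
        if (length(h) == 0L) next
        red <- GenomicRanges::reduce(h, ignore.strand = FALSE)
        if (length(red) == 1L && sum(width(h)) == w[i] &&
            width(red) == w[i]) {
            ok[i] <- TRUE
            out[[i]] <- red
        }
    }
    mapped <- regions[0]
    if (any(ok)) {
        red <- unlist(GenomicRanges::GRangesList(out[ok]))
        mapped <- GRanges(seqnames(red), ranges(red), strand = strand(red))
        names(mapped) <- names(regions)[ok]
        mapped <- mapped[order(as.character(seqnames(mapped)),
                               start(mapped))]
    }
    metadata(mapped)$assembly <- chain@to
    list(mapped = mapped,
         unmapped = names(regions)[!ok],
         remapRate = sum(ok) / length(regions))
}

#' Write a simple chain file from block descriptions
#'
#' Utility for constructing small alignment chains programmatically (used
#' by the simulator and tests). Each chain is a data.frame of colinear
#' ungapped blocks on one (source chromosome, target chromosome, strand).
#'
#' @param chains A list of data.frames with columns \code{tName},
#'   \code{tSize}, \code{tStart}, \code{qName}, \code{qSize}, \code{qStart},
#'   \code{size} (block length, bp); rows are consecutive blocks of one
#'   chain, coordinates 0-based on the plus strand of both sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeChainFile <- function(chains, path) {
    con <- file(path, "w")
    on.exit(close(con))
    num <- function(x) format(x, scientific = FALSE, trim = TRUE)
    id <- 0L
    for (bl in chains) {
        id <- id + 1L
        tEnd <- bl$tStart[nrow(bl)] + bl$size[nrow(bl)]
        qEnd <- bl$qStart[nrow(bl)] + bl$size[nrow(bl)]
        writeLines(paste("chain", 1000L, bl$tName[1L], num(bl$tSize[1L]),
                         "+", num(bl$tStart[1L]), num(tEnd), bl$qName[1L],
                         num(bl$qSize[1L]), "+", num(bl$qStart[1L]),
                         num(qEnd), id), con)
        for (i in seq_len(nrow(bl))) {
            if (i < nrow(bl)) {
                dt <- bl$tStart[i + 1L] - (bl$tStart[i] + bl$size[i])
                dq <- bl$qStart[i + 1L] - (bl$qStart[i] + bl$size[i])
                writeLines(paste(num(bl$size[i]), num(dt), num(dq)), con)
            } else {
                writeLines(num(bl$size[i]), con)
            }
        }
        writeLines("", con)
    }
    invisible(path)
}
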