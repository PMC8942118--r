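#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importFrom S4Vectors metadata
NULL

#' Quantification window configuration
#'
#' Describes the window geometry and normalization used when computing
#' per-region occupancy ("Q-values"). The window is placed around an anchor
#' point of each region: the strand-aware 5' gene start (\code{"gene_start"},
#' the default, placing the window immediately around the transcription start
#' where TFIIIB sits at Pol III genes) or the region centre
#' (\code{"gene_centre"}).
#'
#' @slot upstream Integer, bp extent of the window in the 5' direction
#'   from the anchor (default 500).
#' @slot downstream Integer, bp extent in the 3' direction (default 500).
#' @slot anchor Either \code{"gene_start"} or \code{"gene_centre"}.
#' @slot rpm Logical; normalize raw counts to fragments per million
#'   (default \code{TRUE}).
#' @slot perKb Logical; additionally divide by window length in kb
#'   (default \code{FALSE}).
#'
#' @seealso [quantConfig()], [quantifyRegions()]
#' @exportClass QuantConfig
setClass("QuantConfig",
    representation(
        upstream   = "integer",
        downstream = "integer",
        anchor     = "character",
        rpm        = "logical",
        perKb      = "logical"
    )
)

setValidity("QuantConfig", function(object) {
    msg <- character()
    if (length(object@upstream) != 1L || is.na(object@upstream) ||
        object@upstream < 0L)
        msg <- c(msg, "'upstream' must be a single non-negative integer")
    if (length(object@downstream) != 1L || is.na(object@downstream) ||
        object@downstream < 0L)
        msg <- c(msg, "'downstream' must be a single non-negative integer")
    if (length(object@upstream) == 1L && length(object@downstream) == 1L &&
        !is.na(object@upstream) && !is.na(object@downstream) &&
        object@upstream + object@downstream <= 0L)
        msg <- c(msg, "window length upstream + downstream must be > 0")
    if (!object@anchor %in% c("gene_start", "gene_centre"))
        msg <- c(msg, "'anchor' must be 'gene_start' or 'gene_centre'")
    if (length(msg)) msg else TRUE
})

#' A sequencing library as DNA fragments
#'
#' Holds the inferred DNA fragments of a ChIP-seq library together with the
#' total library size used for per-million normalization. The stored
#' fragments may be a subset of the library (e.g. only those falling on the
#' chromosomes under study); \code{librarySize} always refers to the whole
#' library, so \code{librarySize >= length(fragments)}.
#'
#' @slot fragments A \code{GRanges} of fragment intervals (0-based half-open
#'   on import; stored 1-based as usual for \code{GRanges}).
#' @slot librarySize Numeric scalar, total number of DNA fragments in the
#'   library.
#' @slot source Character scalar describing input format and fragment
#'   inference ("paired", "extended:<bp>", "bed", "simulated", ...).
#'
#' @seealso [readFragments()], [simulateChip()]
#' @exportClass FragmentSet
setClass("FragmentSet",
    representation(
        fragments   = "GRanges",
        librarySize = "numeric",
        source      = "character"
    )
)

setValidity("FragmentSet", function(object) {
    msg <- character()
    if (length(object@librarySize) != 1L || is.na(object@librarySize) ||
        object@librarySize < 0)
        msg <- c(msg, "'librarySize' must be a single non-negative number")
    if (length(object@librarySize) == 1L && !is.na(object@librarySize) &&
        object@librarySize < length(object@fragments))
        msg <- c(msg, "'librarySize' must be >= number of stored fragments")
    if (length(msg)) msg else TRUE
})

#' Per-region occupancy table
#'
#' One row per region: raw fragment count in the quantification window and
#' the normalized occupancy Q (fragments per million when RPM normalization
#' is on). Row order reflects the construction or ranking applied.
#'
#' @slot table A \code{data.frame} with columns \code{name}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{raw}, \code{Q}.
#' @slot config The \code{QuantConfig} used.
#' @slot librarySize Numeric, library size of the source \code{FragmentSet}.
#'
#' @seealso [quantifyRegions()], [rankRegions()], [topRegions()]
#' @exportClass QTable
setClass("QTable",
    representation(
        table       = "data.frame",
        config      = "ANY",
        librarySize = "numeric"
    )
)

setValidity("QTable", function(object) {
    msg <- character()
    need <- c("name", "chrom", "start", "end", "strand", "raw", "Q")
    if (!all(need %in% colnames(object@table)))
        msg <- c(msg, paste0("table must have columns: ",
                             paste(need, collapse = ", ")))
    else {
        if (anyDuplicated(object@table$name))
            msg <- c(msg, "region names must be unique")
        if (any(object@table$Q < 0))
            msg <- c(msg, "Q values must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' Regions-by-bins signal matrix
#'
#' Normalized ChIP signal (fragments per million overlapping each bin) for a
#' set of regions around a common anchor, suitable for ranked heatmaps and
#' metagene averaging. Bin offsets are relative to the anchor; rows follow
#' the ordering of the supplied occupancy table.
#'
#' @slot values Numeric matrix, regions x bins, all values >= 0.
#' @slot binMid Numeric vector of bin midpoint offsets (bp) from the anchor.
#' @slot anchor \code{"gene_centre"} or \code{"gene_start"}.
#' @slot flank Integer, half-window extent (bp).
#' @slot binSize Integer, bin width (bp).
#'
#' @seealso [signalMatrix()], [averageProfile()]
#' @exportClass SignalMatrix
setClass("SignalMatrix",
    representation(
        values  = "matrix",
        binMid  = "numeric",
        anchor  = "character",
        flank   = "integer",
        binSize = "integer"
    )
)

setValidity("SignalMatrix", function(object) {
    msg <- character()
    if (ncol(object@values) != length(object@binMid))
        msg <- c(msg, "ncol(values) must equal length(binMid)")
    if (ncol(object@values) != 2L * object@flank %/% object@binSize)
        msg <- c(msg, "number of bins must equal 2*flank/binSize")
    if (any(object@values < 0))
        msg <- c(msg, "signal values must be non-negative")
    if (is.null(rownames(object@values)))
        msg <- c(msg, "values must carry region names as rownames")
    if (length(msg)) msg else TRUE
})

#' Position weight matrix with background model and exact score distribution
#'
#' Column-stochastic base probabilities over A/C/G/T, a background
#' distribution, per-column log2 odds scores, and the exact distribution of
#' the total log-odds score of a background-generated sequence of the motif
#' width, computed by dynamic programming on a discretized score lattice.
#' The distribution supports exact tail p-values for scan hits.
#'
#' @slot name Motif name.
#' @slot probs 4 x width matrix of column probabilities (rows A, C, G, T).
#' @slot background Length-4 background probabilities (A, C, G, T).
#' @slot pseudocount Pseudocount used if built from counts or consensus.
#' @slot logOdds 4 x width matrix, log2(probs/background).
#' @slot scoreDist List with the discretized score lattice: \code{grain}
#'   (bin width in bits), \code{scores} (bin score values) and \code{tail}
#'   (P(score >= bin value) under the background).
#'
#' @seealso [consensusToPWM()], [countsToPWM()], [scanSequence()],
#'   [pwmPvalue()]
#' @exportClass PWM
setClass("PWM",
    representation(
        name        = "character",
        probs       = "matrix",
        background  = "numeric",
        pseudocount = "numeric",
        logOdds     = "matrix",
        scoreDist   = "list"
    )
)

setValidity("PWM", function(object) {
    msg <- character()
    if (nrow(object@probs) != 4L)
        msg <- c(msg, "probs must have 4 rows (A, C, G, T)")
    if (ncol(object@probs) < 1L)
        msg <- c(msg, "motif width must be >= 1")
    if (any(abs(colSums(object@probs) - 1) > 1e-9))
        msg <- c(msg, "each probs column must sum to 1")
    if (length(object@background) != 4L ||
        abs(sum(object@background) - 1) > 1e-9)
        msg <- c(msg, "background must be 4 probabilities summing to 1")
    if (length(msg)) msg else TRUE
})

#' Assembly-to-assembly coordinate map
#'
#' Wraps a UCSC chain alignment together with source and target assembly
#' labels. Used by [liftoverRegions()] with a strict mapping rule: a region
#' remaps successfully only if every base maps through one chain to a single
#' contiguous target interval.
#'
#' @slot chain An \code{rtracklayer} \code{Chain} object.
#' @slot from Source assembly label (e.g. "hg38").
#' @slot to Target assembly label (e.g. "hg18").
#'
#' @seealso [readChain()], [liftoverRegions()]
#' @exportClass ChainMap
setClass("ChainMap",
    representation(
        chain = "ANY",
        from  = "character",
        to    = "character"
    )
)

#' A synthetic genome with annotations and planted ground truth
#'
#' Output of [makeGenome()]: background sequence, annotated Pol III gene
#' sets (tDNA, snoRNA, miRNA), optional control loci (a bound GREB1-like
#' gene with a full ERE planted 585 bp upstream of its start, and an
#' unbound BC200-like gene), and a truth table recording planted motif
#' offsets per locus.
#'
#' @slot sequence A \code{DNAStringSet}, one entry per chromosome.
#' @slot tdna,snorna,mirna Named \code{GRanges} annotation sets.
#' @slot control Named \code{GRanges} of control loci (may be empty).
#' @slot truth \code{data.frame}: per-locus class, planted motif offsets.
#' @slot config The \code{SimConfig}-style list used for construction.
#'
#' @seealso [makeGenome()], [simulateChip()]
#' @exportClass SyntheticGenome
setClass("SyntheticGenome",
    representation(
        sequence = "ANY",
        tdna     = "GRanges",
        snorna   = "GRanges",
        mirna    = "GRanges",
        control  = "GRanges",
        truth    = "data.frame",
        config   = "list"
    )
)
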