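#' @rdname FragmentSet-class
#' @param x,object A \code{FragmentSet}, \code{QTable}, \code{SignalMatrix}
#'   or \code{PWM} as appropriate.
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @rdname FragmentSet-class
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))

#' @rdname QTable-class
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))

#' @rdname QTable-class
#' @export
setGeneric("qTable", function(x) standardGeneric("qTable"))

#' @rdname QTable-class
#' @export
setGeneric("rawCounts", function(x) standardGeneric("rawCounts"))

#' @rdname SignalMatrix-class
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' @rdname SignalMatrix-class
#' @export
setGeneric("binOffsets", function(x) standardGeneric("binOffsets"))

#' @rdname PWM-class
#' @export
setGeneric("motifWidth", function(x) standardGeneric("motifWidth"))

#' @rdname PWM-class
#' @export
setGeneric("logOdds", function(x) standardGeneric("logOdds"))

# ---- accessors ----

#' @describeIn FragmentSet-class Fragment intervals as a GRanges.
#' @export
setMethod("fragments", "FragmentSet", function(x) x@fragments)

#' @describeIn FragmentSet-class Total fragments in the library.
#' @export
setMethod("librarySize", "FragmentSet", function(x) x@librarySize)

#' @describeIn QTable-class Library size behind the Q normalization.
#' @export
setMethod("librarySize", "QTable", function(x) x@librarySize)

#' @describeIn QTable-class Named vector of Q values.
#' @export
setMethod("qValues", "QTable", function(x)
    stats::setNames(x@table$Q, x@table$name))

#' @describeIn QTable-class The full per-region table as a data.frame.
#' @export
setMethod("qTable", "QTable", function(x) x@table)

#' @describeIn QTable-class Named vector of raw window counts.
#' @export
setMethod("rawCounts", "QTable", function(x)
    stats::setNames(x@table$raw, x@table$name))

#' @describeIn SignalMatrix-class The regions x bins value matrix.
#' @export
setMethod("signalValues", "SignalMatrix", function(x) x@values)

#' @describeIn SignalMatrix-class Bin midpoint offsets from the anchor (bp).
#' @export
setMethod("binOffsets", "SignalMatrix", function(x) x@binMid)

#' @describeIn PWM-class Motif width (number of columns).
#' @export
setMethod("motifWidth", "PWM", function(x) ncol(x@probs))

#' @describeIn PWM-class The 4 x width log2-odds score matrix.
#' @export
setMethod("logOdds", "PWM", function(x) x@logOdds)

# ---- show methods ----

setMethod("show", "QuantConfig", function(object) {
    cat("QuantConfig: window -", object@upstream, "/ +", object@downstream,
        "bp around", object@anchor,
        if (object@rpm) "| RPM" else "| raw counts",
        if (object@perKb) "| per kb" else "", "\n")
})

setMethod("show", "FragmentSet", function(object) {
    cat("FragmentSet with", length(object@fragments),
        "stored fragments (library size",
        format(object@librarySize, big.mark = ","),
        ") source:", object@source, "\n")
})

setMethod("show", "QTable", function(object) {
    cat("QTable with", nrow(object@table), "regions; library size",
        format(object@librarySize, big.mark = ","), "\n")
    print(utils::head(object@table, 5L))
    if (nrow(object@table) > 5L) cat("...\n")
})

setMethod("show", "SignalMatrix", function(object) {
    cat("SignalMatrix:", nrow(object@values), "regions x",
        ncol(object@values), "bins of", object@binSize, "bp; +/-",
        object@flank, "bp around", object@anchor, "\n")
})

setMethod("show", "PWM", function(object) {
    cat("PWM", object@name, "- width", ncol(object@probs),
        sprintf("- max score %.2f bits\n", sum(apply(object@logOdds, 2, max))))
})

setMethod("show", "ChainMap", function(object) {
    cat("ChainMap:", object@from, "->", object@to, "(",
        length(object@chain), "chromosomes )\n")
})

setMethod("show", "SyntheticGenome", function(object) {
    cat("SyntheticGenome:", length(object@sequence), "chromosomes,",
        length(object@tdna), "tDNAs,", length(object@snorna), "snoRNAs,",
        length(object@mirna), "miRNAs,", length(object@control),
        "control loci\n")
})
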