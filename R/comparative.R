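#' Regions bound above an occupancy threshold
#'
#' Returns the names of regions with Q strictly greater than the threshold
#' (Q = 0.5 is excluded at the default threshold of 0.5). If a liftover was
#' applied upstream, regions that failed to remap should already be absent
#' from the table and are thereby excluded from the universe.
#'
#' @param q A [QTable-class].
#' @param threshold Strict lower bound on Q (default 0.5).
#' @return Character vector of region names.
#' @export
boundSet <- function(q, threshold = 0.5) {
    tab <- qTable(q)
    tab$name[tab$Q > threshold]
}

#' Overlap of two or three bound-region sets
#'
#' Standard inclusion-exclusion cell counts for a Venn diagram of region
#' name sets (e.g. [boundSet()] results from different samples).
#'
#' @param sets Named list of 2 or 3 character vectors with distinct names.
#' @return A list: \code{labels}, \code{counts} (named vector of disjoint
#'   cells, names like \code{"A"}, \code{"A&B"}), \code{unionSize} and
#'   \code{threshold} (\code{NA} unless supplied).
#' @param threshold Optional threshold annotation carried through.
#' @examples
#' vennCounts(list(MCF7 = c("a", "b", "c"), GO = c("b", "c", "d")))
#' @export
vennCounts <- function(sets, threshold = NA_real_) {
    if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L)
        stop("'sets' must be a named list of 2 or 3 name vectors",
             call. = FALSE)
    labs <- names(sets)
    if (is.null(labs) || anyDuplicated(labs) || any(!nzchar(labs)))
        stop("set names must be distinct and non-empty", call. = FALSE)
    sets <- lapply(sets, unique)
    universe <- unique(unlist(sets))
    member <- vapply(sets, function(s) universe %in% s,
                     logical(length(universe)))
    if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
    # cell keys use alphabetical label order so that counts are invariant
    # under permutation of the input sets
    key <- apply(member, 1L, function(row)
        paste(sort(labs[row]), collapse = "&"))
    cells <- unlist(lapply(seq_along(labs), function(k)
        utils::combn(sort(labs), k, paste, collapse = "&")))
    counts <- stats::setNames(integer(length(cells)), cells)
    tt <- table(key)
    counts[names(tt)] <- as.integer(tt)
    list(labels = labs, counts = counts,
         unionSize = length(universe), threshold = threshold)
}

#' Classify top-bound genes against a category table
#'
#' Exact name-match lookup after canonical normalization (case-,
#' hyphen- and underscore-insensitive, so "tRNA-Pro-TGG-1-1" and
#' "trna_pro_tgg_1_1" match). Genes absent from the table are tallied as
#' \code{unclassified}.
#'
#' @param top Named \code{GRanges} of top-bound regions (from
#'   [topRegions()]), optionally carrying a \code{Q} metadata column.
#' @param categories A data.frame with columns \code{name} and
#'   \code{category} (values among proliferation/differentiation/other), or
#'   a path to such a two-column TSV.
#' @return A list: \code{tally} (named counts for proliferation,
#'   differentiation, other, unclassified) and \code{perGene} (data.frame
#'   of name, category and Q where available).
#' @export
classifyTop <- function(top, categories) {
    if (is.character(categories) && length(categories) == 1L)
        categories <- utils::read.delim(categories,
                                        stringsAsFactors = FALSE)
    if (!all(c("name", "category") %in% names(categories)))
        stop("categories need 'name' and 'category' columns", call. = FALSE)
    ok <- categories$category %in%
        c("proliferation", "differentiation", "other")
    if (any(!ok))
        stop("invalid category value(s): ",
             paste(unique(categories$category[!ok]), collapse = ", "),
             call. = FALSE)
    canon <- function(x) tolower(gsub("[-_]", "", x))
    if (anyDuplicated(canon(categories$name)))
        stop("duplicate gene names in category table", call. = FALSE)
    lut <- stats::setNames(categories$category, canon(categories$name))
    cls <- lut[canon(names(top))]
    cls[is.na(cls)] <- "unclassified"
    lv <- c("proliferation", "differentiation", "other", "unclassified")
    tally <- table(factor(cls, levels = lv))
    perGene <- data.frame(name = names(top), category = unname(cls))
    if (!is.null(top$Q)) perGene$Q <- top$Q
    list(tally = stats::setNames(as.integer(tally), lv), perGene = perGene)
}

.SIG_LADDER <- c(0.05, 0.01, 0.001, 0.0001)

.sigLabel <- function(p) {
    vapply(p, function(x) {
        if (is.na(x)) NA_character_
        else if (x < 1e-4) "****"
        else if (x < 1e-3) "***"
        else if (x < 1e-2) "**"
        else if (x < 0.05) "*"
        else "ns"
    }, "")
}

#' Compare occupancy distributions between samples
#'
#' Pairwise two-sided Mann-Whitney (Wilcoxon rank-sum) tests on the
#' per-region Q values of two or more samples quantified over the same
#' region universe, with Holm adjustment across pairs and a significance
#' label on the conventional 0.05/0.01/0.001/0.0001 ladder. The test is
#' unpaired: occupancy distributions are compared as samples, not matched
#' per region.
#'
#' @param tables Named list (>= 2) of [QTable-class] objects over an
#'   identical region universe.
#' @return A data.frame: \code{sample1}, \code{sample2}, \code{U}
#'   (Mann-Whitney statistic of sample1 vs sample2), \code{p.value},
#'   \code{p.adjusted} (Holm), \code{label}.
#' @export
compareQDistributions <- function(tables) {
    if (!is.list(tables) || length(tables) < 2L)
        stop("need >= 2 QTables", call. = FALSE)
    labs <- names(tables)
    if (is.null(labs) || anyDuplicated(labs))
        stop("tables must carry unique names", call. = FALSE)
    universes <- lapply(tables, function(q) sort(qTable(q)$name))
    ref <- universes[[1L]]
    for (i in seq_along(universes)[-1L]) {
        miss <- c(setdiff(ref, universes[[i]]),
                  setdiff(universes[[i]], ref))
        if (length(miss))
            stop("region universe mismatch between '", labs[1L], "' and '",
                 labs[i], "': ", paste(utils::head(miss, 5L),
                                       collapse = ", "), call. = FALSE)
    }
    pairs <- utils::combn(labs, 2L)
    res <- data.frame(sample1 = pairs[1L, ], sample2 = pairs[2L, ],
                      U = NA_real_, p.value = NA_real_)
    for (k in seq_len(ncol(pairs))) {
        x <- qValues(tables[[pairs[1L, k]]])
        y <- qValues(tables[[pairs[2L, k]]])
        wt <- suppressWarnings(stats::wilcox.test(x, y,
                                                  alternative = "two.sided"))
        res$U[k] <- unname(wt$statistic)
        res$p.value[k] <- wt$p.value
    }
    res$p.adjusted <- stats::p.adjust(res$p.value, method = "holm")
    res$label <- .sigLabel(res$p.adjusted)
    res
}
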