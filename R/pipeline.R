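#' Run the occupancy pipeline end to end
#'
#' Orchestrates simulate-or-load, windowed quantification, ranking,
#' signal matrices and metagene profiles, motif interrogation of the
#' top-bound genes, threshold overlap between samples, category
#' classification, and distribution comparison, from one declarative
#' configuration. Every produced file is recorded in a JSON manifest with
#' its MD5 hash, so a rerun with an identical configuration and seed can
#' be verified byte for byte.
#'
#' Configuration fields (list or YAML file):
#' \describe{
#'   \item{outDir}{Output directory (required).}
#'   \item{seed}{Seed for simulation profiles (default 1).}
#'   \item{simulate}{Named list sample -> profile
#'     (\code{"mcf7_like"}, \code{"mda_like"}, \code{"met3_like"}), plus
#'     optional \code{simConfig} overrides under \code{simulate$config}.}
#'   \item{samples}{Named list sample -> fragment file (BED/SAM/BAM);
#'     exactly one of \code{simulate}/\code{samples} per sample name.}
#'   \item{regions}{BED6 path of regions (required with \code{samples}).}
#'   \item{genome}{FASTA path (optional; enables motif scanning).}
#'   \item{categories}{Two-column TSV gene -> category (optional).}
#'   \item{quant}{List: upstream, downstream (default 500/500).}
#'   \item{profiles}{List: flank (default 10000), binSize (default 50).}
#'   \item{motifs}{List: flank (default 20000), minP (default 5e-4),
#'     topN (default 19, the number of strongest-bound genes scanned).}
#'   \item{threshold}{Bound-set Q threshold (default 0.5).}
#'   \item{topN}{Genes kept for category analysis (default 50).}
#' }
#'
#' @param config Configuration list or path to a YAML file.
#' @return The manifest (named list), invisibly; also written as
#'   \code{manifest.json} in \code{outDir}.
#' @export
runPipeline <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    if (is.null(config$outDir))
        stop("config$outDir is required", call. = FALSE)
    simNames <- names(config$simulate)
    simNames <- simNames[simNames != "config"]
    realNames <- names(config$samples)
    if (length(intersect(simNames, realNames)))
        stop("sample(s) configured both simulated and real: ",
             paste(intersect(simNames, realNames), collapse = ", "),
             call. = FALSE)
    if (length(simNames) + length(realNames) == 0L)
        stop("no samples configured", call. = FALSE)
    for (p in unlist(config$samples))
        if (!file.exists(p)) stop("missing input: ", p, call. = FALSE)
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    outDir <- config$outDir
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    getpar <- function(block, field, default) {
        v <- config[[block]][[field]]
        if (is.null(v)) default else v
    }
    qcfg <- quantConfig(getpar("quant", "upstream", 500L),
                        getpar("quant", "downstream", 500L))
    flank <- getpar("profiles", "flank", 10000L)
    binSize <- getpar("profiles", "binSize", 50L)
    motifFlank <- getpar("motifs", "flank", 20000L)
    minP <- getpar("motifs", "minP", DEFAULT_MIN_P)
    motifTopN <- getpar("motifs", "topN", 19L)
    threshold <- if (is.null(config$threshold)) 0.5 else config$threshold
    topN <- if (is.null(config$topN)) 50L else as.integer(config$topN)
    artifacts <- character()
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    # --- inputs: simulate or load ---
    genomeSeq <- NULL
    regions <- NULL
    fragsets <- list()
    if (length(simNames)) {
        over <- config$simulate$config
        if (is.null(over)) over <- list()
        over$seed <- seed
        scfg <- stage("simulate", do.call(simConfig, over))
        sim <- stage("simulate", makeGenome(scfg))
        genomeSeq <- sim@sequence
        regions <- sim@tdna
        gfiles <- stage("simulate",
                        writeGenomeFiles(sim, file.path(outDir, "genome")))
        artifacts <- c(artifacts, gfiles)
        for (i in seq_along(simNames)) {
            nmv <- simNames[i]
            lib <- stage("simulate",
                         simulateChip(sim, config$simulate[[nmv]],
                                      seed = .deriveSeed(seed, i)))
            fragsets[[nmv]] <- lib$fragments
            fp <- file.path(outDir, paste0(nmv, ".fragments.bed"))
            writeFragmentsBED(lib$fragments, fp)
            artifacts <- c(artifacts, fp)
        }
    }
    if (length(realNames)) {
        if (is.null(config$regions))
            stop("config$regions is required with real samples",
                 call. = FALSE)
        regions <- stage("read_regions", readRegions(config$regions))
        for (nmv in realNames)
            fragsets[[nmv]] <- stage("read_fragments",
                                     readFragments(config$samples[[nmv]]))
        if (!is.null(config$genome))
            genomeSeq <- Biostrings::readDNAStringSet(config$genome)
    }
    # --- quantify + rank ---
    qtabs <- list()
    for (nmv in names(fragsets)) {
        qt <- stage("quantify",
                    rankRegions(quantifyRegions(fragsets[[nmv]], regions,
                                                qcfg)))
        qtabs[[nmv]] <- qt
        qp <- file.path(outDir, paste0(nmv, ".qtable.tsv"))
        writeQTable(qt, qp)
        artifacts <- c(artifacts, qp)
    }
    # --- signal matrices + metagene profiles ---
    for (nmv in names(fragsets)) {
        sm <- stage("signal_matrix",
                    signalMatrix(fragsets[[nmv]], regions,
                                 order = qtabs[[nmv]], flank = flank,
                                 binSize = binSize))
        mp <- file.path(outDir, paste0(nmv, ".matrix.tsv"))
        vals <- signalValues(sm)
        utils::write.table(
            data.frame(name = rownames(vals),
                       stats::setNames(as.data.frame(vals),
                                       binOffsets(sm))),
            mp, sep = "\t", quote = FALSE, row.names = FALSE)
        pp <- file.path(outDir, paste0(nmv, ".profile.tsv"))
        utils::write.table(averageProfile(sm), pp, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        artifacts <- c(artifacts, mp, pp)
    }
    # --- motif interrogation of the strongest-bound genes ---
    if (!is.null(genomeSeq)) {
        first <- qtabs[[1L]]
        nScan <- min(motifTopN, nrow(qTable(first)))
        topGenes <- stage("motifs", topRegions(first, nScan))
        res <- stage("motifs",
                     scanNeighborhood(genomeSeq, topGenes,
                                      flank = motifFlank, minP = minP))
        fm <- file.path(outDir, "motif_found.tsv")
        utils::write.table(
            data.frame(name = rownames(res$found), res$found),
            fm, sep = "\t", quote = FALSE, row.names = FALSE)
        hm <- file.path(outDir, "motif_hits.tsv")
        writeMotifHits(res$hits, hm)
        artifacts <- c(artifacts, fm, hm)
    }
    # --- cross-sample overlap + distribution comparison ---
    if (length(qtabs) >= 2L) {
        sets <- lapply(qtabs, boundSet, threshold = threshold)
        vn <- stage("venn",
                    vennCounts(sets[seq_len(min(3L, length(sets)))],
                               threshold = threshold))
        vp <- file.path(outDir, "venn.json")
        jsonlite::write_json(vn, vp, auto_unbox = TRUE, digits = NA)
        cmp <- stage("compare", compareQDistributions(qtabs))
        cp <- file.path(outDir, "comparisons.tsv")
        utils::write.table(cmp, cp, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        artifacts <- c(artifacts, vp, cp)
    }
    # --- category classification of the top-bound genes ---
    if (!is.null(config$categories)) {
        cls <- stage("classify",
                     classifyTop(topRegions(qtabs[[1L]],
                                            min(topN,
                                                nrow(qTable(qtabs[[1L]])))),
                                 config$categories))
        tp <- file.path(outDir, "category_tally.tsv")
        utils::write.table(
            data.frame(category = names(cls$tally), n = cls$tally),
            tp, sep = "\t", quote = FALSE, row.names = FALSE)
        artifacts <- c(artifacts, tp)
    }
    manifest <- list(
        seed = seed,
        samples = names(fragsets),
        artifacts = lapply(stats::setNames(nm = unname(artifacts)),
                           function(p)
                               list(md5 = unname(tools::md5sum(p)))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
}
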