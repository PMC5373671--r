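#' Pipeline configuration
#'
#' One validated configuration for an end-to-end run.  Stage parameters
#' default to the pipeline's standard settings: caller error rate 0.01
#' at test level 0.05, depth filters 6/28 reads, unique-mapping fraction
#' 0.90, indel buffer 500 bp, final segments of at least 5 SNPs at FDR
#' 5%, analyzable regions of more than 7 SNPs with at most 30% missing
#' lines per group, 10 kb genic flanks, 50 kb control distance, and
#' 1000 SUMSTAT resamples.  Unknown keys are rejected.
#'
#' @param outDir output directory for stage artifacts.
#' @param seed global seed; stage seeds are derived from it.
#' @param stages named logical list toggling the stages
#'   (simulate, call, segment, diversity, scan, networks, f3).
#' @param sim overrides passed to \code{\link{simConfig}}.
#' @param caller overrides passed to \code{\link{callerConfig}}.
#' @param segment list(fdr, minSnps, Kmax).
#' @param diversity list(window, step, project).
#' @param scan list(flank, controlDistance, nControls, minSnps,
#'   maxMissing, alpha).
#' @param networks list(nResample, nBins).
#' @param f3 list(blockSize, minBlocks).
#' @return validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(outDir = tempfile("inbredscan"), seed = 1L,
                           stages = list(), sim = list(), caller = list(),
                           segment = list(), diversity = list(),
                           scan = list(), networks = list(), f3 = list()) {
    stageNames <- c("simulate", "call", "segment", "diversity", "scan",
                    "networks", "f3")
    st <- stats::setNames(as.list(rep(TRUE, length(stageNames))), stageNames)
    checkKeys <- function(given, allowed, where) {
        bad <- setdiff(names(given), allowed)
        if (length(bad))
            stop("unknown ", where, " keys: ", paste(bad, collapse = ", "))
        given
    }
    st[names(checkKeys(stages, stageNames, "stage"))] <- stages
    defaults <- list(
        segment = list(fdr = 0.05, minSnps = 5L, Kmax = 30L),
        diversity = list(window = 50000L, step = 10000L, project = 29L),
        scan = list(flank = 10000L, controlDistance = 50000L,
                    nControls = 300L, minSnps = 7L, maxMissing = 0.3,
                    alpha = 0.05),
        networks = list(nResample = 1000L, nBins = 20L),
        f3 = list(blockSize = 25L, minBlocks = 100L))
    merge1 <- function(name, given) {
        d <- defaults[[name]]
        d[names(checkKeys(given, names(d), name))] <- given
        d
    }
    cfg <- list(outDir = outDir, seed = as.integer(seed), stages = st,
                sim = checkKeys(sim, names(formals(simConfig)), "sim"),
                caller = checkKeys(caller, names(formals(callerConfig)),
                                   "caller"),
                segment = merge1("segment", segment),
                diversity = merge1("diversity", diversity),
                scan = merge1("scan", scan),
                networks = merge1("networks", networks),
                f3 = merge1("f3", f3))
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order (simulate -> call ->
#' segment -> diversity -> scan -> networks -> f3) on synthetic data
#' with known truth, writing each stage's tables, a line-oriented log
#' and a configuration echo (with the seed) to \code{outDir}.  A
#' disabled upstream stage required by an enabled downstream stage
#' raises a dependency error.  Reruns with an identical configuration
#' produce identical outputs.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return (invisibly) a list with the in-memory stage results and the
#'   output directory.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    st <- config$stages
    logFile <- file.path(config$outDir, "pipeline.log")
    cat(NULL, file = logFile)
    logline <- function(...) {
        msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
        cat(msg, "\n", file = logFile, append = TRUE, sep = "")
    }
    echo <- config; echo$stages <- unlist(st)
    jsonlite::write_json(echo, file.path(config$outDir, "config.json"),
                         auto_unbox = TRUE, force = TRUE, digits = NA)
    need <- function(dep, stage) {
        if (!isTRUE(st[[dep]]))
            stop("stage '", stage, "' requires stage '", dep,
                 "' to be enabled", call. = FALSE)
    }
    res <- list(outDir = config$outDir)
    writeTsv <- function(x, name)
        data.table::fwrite(x, file.path(config$outDir, name), sep = "\t")

    if (isTRUE(st$simulate)) {
        logline("simulate: seed=", config$seed)
        simArgs <- config$sim
        simArgs$seed <- config$seed
        cfg <- do.call(simConfig, simArgs)
        res$simCfg <- cfg
        struct <- simulateStructuredGenotypes(cfg)
        res$genotypes <- struct$calls
        res$truth <- struct$truth
        hp <- simulateHetProfiles(cfg)
        res$hetProfile <- hp$profile
        res$hetTruth <- hp$truth
        cfgClean <- cfg; cfgClean$missingRate <- 0
        class(cfgClean) <- "SimConfig"
        truthCalls <- simulateStructuredGenotypes(cfgClean)$calls
        res$readCounts <- simulateReadCounts(truthCalls, cfg)
        res$truthCalls <- truthCalls
        genomeLength <- (cfg$nSites + 1) * cfg$siteSpacing
        sweepsBp <- lapply(cfg$sweepRegions, function(s)
            list(start = s$start * cfg$siteSpacing,
                 end = s$end * cfg$siteSpacing,
                 direction = paste0("G", s$group)))
        buffer <- config$scan$controlDistance
        geneLength <- 3000L
        nGenes <- min(60L, genomeLength %/% (geneLength + 2L * buffer + 2048L))
        sweepsGr <- if (length(sweepsBp)) GRanges("chr1", IRanges(
            vapply(sweepsBp, `[[`, numeric(1), "start"),
            vapply(sweepsBp, `[[`, numeric(1), "end"))) else NULL
        emitArgs <- list(genomeLength = genomeLength,
                         nGenes = max(1L, nGenes),
                         geneLength = geneLength, buffer = buffer,
                         sweepRegions = sweepsGr,
                         plantNetwork = length(sweepsBp) > 0,
                         seed = config$seed + 1L)
        res$annot <- tryCatch(do.call(emitAnnotationsAndNetworks, emitArgs),
                              error = function(e) {
            ## sweeps too narrow to seed a network of > 5 genes
            logline("simulate: no planted network (", conditionMessage(e),
                    ")")
            emitArgs$plantNetwork <- FALSE
            do.call(emitAnnotationsAndNetworks, emitArgs)
        })
        res$xpclr <- simulateXpclrScores(
            genomeLength,
            directions = paste0("G", c(1, 2)),
            sweeps = if (length(sweepsBp)) sweepsBp else NULL,
            seed = config$seed + 2L)
        writeTsv(data.frame(line = colnames(genoMatrix(res$genotypes)),
                            group = lineGroups(res$genotypes)),
                 "groups.tsv")
        writeTsv(res$annot$networks, "networks.tsv")
        writeTsv(res$xpclr, "xpclr_scores.tsv")
        writeTsv(as.data.frame(res$annot$genes), "genes.tsv")
        jsonlite::write_json(
            list(seed = config$seed,
                 sweptSites = which(res$truth$sweptSites),
                 plantedSegments = res$hetTruth$segments,
                 plantedNetwork = res$annot$plantedNetwork),
            file.path(config$outDir, "truth.json"),
            auto_unbox = TRUE, digits = NA)
    }

    if (isTRUE(st$call)) {
        need("simulate", "call")
        logline("call: epsilon/alpha per caller config")
        ccArgs <- do.call(callerConfig, config$caller)
        cf <- callAndFilter(res$readCounts, ccArgs)
        res$calls <- cf$calls
        res$filterReport <- cf$report
        writeTsv(cf$report, "filter_report.tsv")
        writeTsv(data.frame(line = names(perLineHetRate(cf$calls)),
                            hetRate = perLineHetRate(cf$calls)),
                 "per_line_het.tsv")
    }

    if (isTRUE(st$segment)) {
        need("simulate", "segment")
        logline("segment: Kmax=", config$segment$Kmax)
        hs <- hetSegments(res$hetProfile, Kmax = config$segment$Kmax,
                          fdr = config$segment$fdr,
                          minSnps = config$segment$minSnps)
        res$segments <- hs
        segs <- hs$segments
        writeTsv(segs, "segments.tsv")
        if (nrow(segs)) {
            bed <- data.frame(chrom = segs$chrom,
                              start = segs$startBp - 1L,  # BED half-open
                              end = segs$endBp,
                              name = sprintf("seg%03d", seq_len(nrow(segs))),
                              score = round(-10 * log10(pmax(segs$p,
                                                             1e-12))),
                              strand = ".")
            data.table::fwrite(bed, file.path(config$outDir,
                                              "segments.bed"),
                               sep = "\t", col.names = FALSE)
        }
    }

    if (isTRUE(st$diversity)) {
        need("simulate", "diversity")
        logline("diversity: window=", config$diversity$window)
        ws <- windowScan(res$genotypes, window = config$diversity$window,
                         step = config$diversity$step)
        res$windows <- ws
        writeTsv(ws, "window_stats.tsv")
        m <- min(config$diversity$project,
                 max(2, min(rowSums(!is.na(haploidDosage(res$genotypes))))))
        sfs <- buildSfs(res$genotypes, m = m)
        res$sfs <- sfs
        writeTsv(data.frame(class = names(sfs$sfs), count = sfs$sfs),
                 "sfs.tsv")
    }

    if (isTRUE(st$scan)) {
        need("simulate", "scan")
        logline("scan: controls=", config$scan$nControls)
        genomeLength <- max(end(res$annot$nongenic))
        regions <- partitionRegions(res$annot$genes, genomeLength,
                                    flank = config$scan$flank,
                                    controlDistance =
                                        config$scan$controlDistance,
                                    nControls = config$scan$nControls,
                                    seed = config$seed + 3L)
        grp <- unique(lineGroups(res$genotypes))[1:2]
        rs <- regionStats(res$genotypes, regions, grp[1], grp[2],
                          minSnps = config$scan$minSnps,
                          maxMissing = config$scan$maxMissing)
        xp <- importXpclr(res$xpclr, regions)
        ctrl <- rs$kind == "nongenic" & !is.na(rs$fst)
        stats <- data.frame(
            region_id = rs$region_id, kind = rs$kind, nSnps = rs$nSnps,
            fst = rs$fst, d1 = rs$dA, d2 = rs$dB,
            fstP = empiricalPvalue(rs$fst, rs$fst[ctrl], "upper",
                                   minControls = 50L),
            dP1 = empiricalPvalue(rs$dA, rs$dA[ctrl], "lower",
                                  minControls = 50L),
            dP2 = empiricalPvalue(rs$dB, rs$dB[ctrl], "lower",
                                  minControls = 50L))
        xCols <- grep("^xpclr_", names(xp), value = TRUE)[1:2]
        ctrlIdx <- which(ctrl)
        stats$xpclrP1 <- empiricalPvalue(xp[[xCols[1]]],
                                         xp[[xCols[1]]][ctrlIdx], "upper",
                                         minControls = 50L)
        stats$xpclrP2 <- empiricalPvalue(xp[[xCols[2]]],
                                         xp[[xCols[2]]][ctrlIdx], "upper",
                                         minControls = 50L)
        cand <- callDsCandidates(stats[stats$kind == "genic", ],
                                 alpha = config$scan$alpha)
        res$regionStats <- stats
        res$candidates <- cand
        writeTsv(stats, "region_stats.tsv")
        writeTsv(cand, "ds_candidates.tsv")
    }

    if (isTRUE(st$networks)) {
        need("scan", "networks")
        logline("networks: resamples=", config$networks$nResample)
        genic <- res$regionStats[res$regionStats$kind == "genic", ]
        genic <- genic[!is.na(genic$fstP), ]
        nCtrl <- sum(res$regionStats$kind == "nongenic")
        z <- pToZ(genic$fstP, nCtrl)
        norm <- binMedianNormalize(z, genic$nSnps,
                                   nBins = config$networks$nBins)
        scores <- data.frame(gene_id = genic$region_id, normZ = norm$normZ)
        nets <- sumstatAll(res$annot$networks, scores,
                           nResample = config$networks$nResample,
                           seed = config$seed + 4L)
        if (!is.null(nets)) {
            sets <- split(res$annot$networks$gene_id,
                          res$annot$networks$network_id)
            cl <- clusterNetworks(sets[nets$network_id])
            nets$cluster <- cl[nets$network_id]
        }
        res$networkResults <- nets
        if (!is.null(nets)) writeTsv(nets, "network_results.tsv")
    }

    if (isTRUE(st$f3)) {
        need("simulate", "f3")
        grp <- unique(lineGroups(res$genotypes))
        if (length(grp) >= 3 && !is.na(res$truth$admixedGroup)) {
            tgt <- paste0("G", res$truth$admixedGroup)
            src <- setdiff(grp, tgt)[1:2]
            f3r <- tryCatch(
                f3Test(res$genotypes, tgt, src[1], src[2],
                       blockSize = config$f3$blockSize,
                       minBlocks = config$f3$minBlocks),
                error = function(e) NULL)
            if (!is.null(f3r)) {
                logline("f3: target=", tgt)
                res$f3 <- f3r
                writeTsv(data.frame(target = tgt, sourceA = src[1],
                                    sourceB = src[2], f3 = f3r$f3,
                                    se = f3r$se, z = f3r$z),
                         "f3.tsv")
            }
        }
    }
    logline("done")
    invisible(res)
}
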