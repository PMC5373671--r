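#' Inverse-normal transform of empirical p-values
#'
#' Z = qnorm(1 - p), so small p (strong differentiation) maps to large
#' positive Z.  p is clamped to \[1/(2N), 1 - 1/(2N)\], N the number of
#' control regions behind the empirical p-values, keeping Z finite.
#'
#' @param p empirical p-values in (0, 1).
#' @param nControls the number of controls N used to compute them.
#' @return numeric Z-scores.
#' @export
pToZ <- function(p, nControls) {
    lo <- 1 / (2 * nControls)
    stats::qnorm(1 - pmin(pmax(p, lo), 1 - lo))
}

#' SNP-count-binned median normalization of gene Z-scores
#'
#' Gene Z-scores correlate with the number of SNPs per gene; genes are
#' grouped into equal-occupancy bins of similar SNP count (default 20)
#' and each gene's Z is centred by its bin median.  Bins with fewer than
#' 5 genes are merged with their neighbor.  A mean-centering variant is
#' available.
#'
#' @param z gene Z-scores.
#' @param snpCount per-gene SNP counts.
#' @param nBins target number of bins (default 20).
#' @param center \code{"median"} (default) or \code{"mean"}.
#' @return list(normZ, bin) -- centred Z-scores and bin ids.
#' @export
binMedianNormalize <- function(z, snpCount, nBins = 20L,
                               center = c("median", "mean")) {
    center <- match.arg(center)
    stopifnot(length(z) == length(snpCount))
    n <- length(z)
    nBins <- max(1L, min(nBins, floor(n / 5)))
    ## equal-occupancy bins on the SNP-count order
    ord <- rank(snpCount, ties.method = "first")
    bin <- ceiling(ord / n * nBins)
    ## merge undersized bins with their left neighbor
    repeat {
        tab <- table(bin)
        small <- as.integer(names(tab))[tab < 5]
        if (!length(small) || length(tab) == 1) break
        b <- small[1]
        target <- if (b > min(bin)) max(bin[bin < b]) else min(bin[bin > b])
        bin[bin == b] <- target
    }
    centerFun <- if (center == "median") stats::median else mean
    med <- tapply(z, bin, centerFun)
    list(normZ = as.vector(z - med[as.character(bin)]), bin = bin)
}

#' SUMSTAT network selection test
#'
#' Scores a gene network as the sum of its genes' normalized Z-scores
#' and evaluates significance by resampling: random gene sets of the
#' network's size are drawn without replacement from all annotated
#' genes, and p = (1 + \#resampled sums >= observed) / (resamples + 1).
#'
#' @param networkGenes character vector of the network's gene ids
#'   (more than 5 required).
#' @param scores data.frame with columns gene_id and normZ (all
#'   annotated genes).
#' @param nResample number of resamples (default 1000).
#' @param seed integer seed for the resampling.
#' @return list(networkSize, sumstat, p.value, missingGenes).
#' @export
sumstatTest <- function(networkGenes, scores, nResample = 1000L,
                        seed = 1L) {
    present <- networkGenes %in% scores$gene_id
    missing <- networkGenes[!present]
    genes <- networkGenes[present]
    if (length(genes) <= 5)
        stop("networks are analyzed only if more than 5 scored genes")
    z <- scores$normZ[match(genes, scores$gene_id)]
    obs <- sum(z)
    set.seed(seed)
    sz <- length(genes)
    sums <- vapply(seq_len(nResample), function(i)
        sum(scores$normZ[sample.int(nrow(scores), sz)]), numeric(1))
    p <- (1 + sum(sums >= obs)) / (nResample + 1)
    list(networkSize = sz, sumstat = obs, p.value = p,
         missingGenes = missing)
}

#' Test every network of a membership table
#'
#' @param networks data.frame (network_id, gene_id).
#' @param scores data.frame (gene_id, normZ).
#' @param nResample resamples per network (default 1000).
#' @param seed integer seed.
#' @return data.frame of per-network size, SUMSTAT and resampling p
#'   (networks with 5 or fewer scored genes are skipped).
#' @export
sumstatAll <- function(networks, scores, nResample = 1000L, seed = 1L) {
    ids <- unique(networks$network_id)
    rows <- lapply(seq_along(ids), function(i) {
        g <- networks$gene_id[networks$network_id == ids[i]]
        if (sum(g %in% scores$gene_id) <= 5) return(NULL)
        r <- sumstatTest(g, scores, nResample, seed = seed + i)
        data.frame(network_id = ids[i], size = r$networkSize,
                   sumstat = r$sumstat, p.value = r$p.value)
    })
    do.call(rbind, rows)
}

#' Cluster gene networks by shared membership
#'
#' Single-linkage clustering of networks whose gene overlap
#' |A intersect B| / min(|A|, |B|) exceeds the threshold: such pairs are
#' connected and clusters are the connected components.
#'
#' @param networkSets named list of gene-id character vectors.
#' @param threshold overlap fraction above which two networks join
#'   (default 0.5).
#' @return named integer vector of cluster ids.
#' @export
clusterNetworks <- function(networkSets, threshold = 0.5) {
    stopifnot(all(lengths(networkSets) > 0))
    ids <- names(networkSets)
    nn <- length(networkSets)
    g <- igraph::make_empty_graph(n = nn, directed = FALSE)
    edges <- c()
    if (nn > 1) {
        for (i in seq_len(nn - 1)) for (j in (i + 1):nn) {
            ov <- length(intersect(networkSets[[i]], networkSets[[j]])) /
                min(length(networkSets[[i]]), length(networkSets[[j]]))
            if (ov > threshold) edges <- c(edges, i, j)
        }
    }
    if (length(edges)) g <- igraph::add_edges(g, edges)
    comp <- igraph::components(g)$membership
    stats::setNames(as.integer(comp), ids)
}

#' One-sided Fisher enrichment of candidate genes in categories
#'
#' For each annotation category, a one-sided (greater) hypergeometric
#' test of candidate-gene over-representation, with the annotated genes
#' as the universe, followed by Benjamini-Hochberg adjustment across
#' categories.
#'
#' @param candidates character vector of candidate gene ids.
#' @param categoryMap data.frame (category, gene_id); the union of its
#'   gene ids is the universe.
#' @return data.frame per category: sizes, overlap, odds ratio, p, q.
#' @export
fisherEnrichment <- function(candidates, categoryMap) {
    universe <- unique(categoryMap$gene_id)
    cand <- intersect(unique(candidates), universe)
    cats <- unique(categoryMap$category)
    rows <- lapply(cats, function(cat) {
        inCat <- unique(categoryMap$gene_id[categoryMap$category == cat])
        if (!length(inCat)) return(NULL)
        k <- length(intersect(cand, inCat))
        tab <- matrix(c(k, length(inCat) - k,
                        length(cand) - k,
                        length(universe) - length(inCat) - length(cand) + k),
                      2, 2)
        ft <- stats::fisher.test(tab, alternative = "greater")
        data.frame(category = cat, categorySize = length(inCat),
                   nCandidates = length(cand), overlap = k,
                   oddsRatio = unname(ft$estimate), p.value = ft$p.value)
    })
    out <- do.call(rbind, rows)
    if (!is.null(out)) out$q.value <- bhAdjust(out$p.value)
    out
}
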