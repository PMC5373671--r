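## Independent oracles used across tests.  These deliberately avoid the
## package's own code paths.

## Exhaustive-enumeration segmentation oracle: best K-segmentation of
## pooled Bernoulli columns, lexicographically smallest breakpoints
## among optima (ties within tol).
bruteSegment <- function(h, m, K, tol = 1e-9) {
    n <- length(h)
    segCost <- function(i, j) {
        H <- sum(h[i:j]); M <- sum(m[i:j])
        if (M == 0) return(0)
        R <- M - H
        cc <- 0
        if (H > 0) cc <- cc - H * log(H / M)
        if (R > 0) cc <- cc - R * log(R / M)
        cc
    }
    combos <- if (K == 1) list(integer(0))
              else utils::combn(n - 1, K - 1, simplify = FALSE)
    best <- Inf; bestbp <- NULL
    for (bp in combos) {
        s <- c(1, bp + 1); e <- c(bp, n)
        v <- sum(mapply(segCost, s, e))
        if (v < best - tol) { best <- v; bestbp <- bp }
        ## lexicographic tie-break: combn enumerates in lexicographic
        ## order, so the first optimum seen is the smallest
    }
    list(logLik = -best, breakpoints = bestbp)
}

## Direct binomial upper-tail summation (naive, small n only)
binomTailOracle <- function(k, n, p) {
    if (k <= 0) return(1)
    sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

## One replicate of the genomic SUMSTAT design: a two-group genome whose
## planted network's genes (and their genic windows) carry a sweep in
## group 1; returns the planted network's resampling p-value.
sumstatPlantedP <- function(seed, nGenes = 60, nPlanted = 10) {
    nSites <- 16000; spacing <- 200
    genomeLength <- (nSites + 1) * spacing
    ann <- emitAnnotationsAndNetworks(genomeLength, nGenes = nGenes,
                                      geneLength = 3000, buffer = 10000,
                                      nNetworks = 5, seed = seed)
    pick <- sort(sample(nGenes, nPlanted))
    sg <- ann$genes[pick]
    sweeps <- lapply(seq_along(sg), function(i) list(
        group = 1,
        start = max(1, (GenomicRanges::start(sg)[i] - 12000) %/% spacing),
        end = min(nSites, (GenomicRanges::end(sg)[i] + 12000) %/% spacing),
        strength = 0.95))
    cfg <- simConfig(seed = seed, nSites = nSites, groupSizes = c(13L, 14L),
                     targetFst = 0.15, sweepRegions = sweeps,
                     missingRate = 0.2)
    gg <- simulateStructuredGenotypes(cfg)
    regions <- partitionRegions(ann$genes, genomeLength, flank = 10000,
                                controlDistance = 10000, nControls = 300,
                                seed = seed + 1)
    rs <- regionStats(gg$calls, regions, "G1", "G2")
    ctrl <- rs$kind == "nongenic" & !is.na(rs$fst)
    genic <- rs[rs$kind == "genic" & !is.na(rs$fst), ]
    fstP <- empiricalPvalue(genic$fst, rs$fst[ctrl], "upper",
                            minControls = 50)
    z <- pToZ(fstP, sum(ctrl))
    nz <- binMedianNormalize(z, genic$nSnps, nBins = 6)$normZ
    scores <- data.frame(gene_id = genic$region_id, normZ = nz)
    sumstatTest(ann$genes$gene_id[pick], scores, nResample = 1000,
                seed = seed + 2)$p.value
}

## random het profile generator for property tests
randomProfile <- function(n, L, rate = 0.25, missing = 0.2) {
    X <- matrix(rbinom(L * n, 1, rate), L, n)
    X[runif(L * n) < missing] <- NA
    ## guarantee no all-missing column
    bad <- colSums(!is.na(X)) == 0
    X[1, bad] <- 0L
    HetProfile(X)
}
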