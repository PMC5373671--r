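#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators.  Defaults emulate
#' the study conditions of a resequenced inbred-line panel: 57 lines,
#' mean sequencing depth 18x, per-read error rate 0.01, genome-wide
#' residual heterozygosity 0.41%, and per-cell missingness around the
#' 18--32% per-line regime typical of mid-depth data.
#'
#' @param seed integer; seeds the single global RNG stream used by each
#'   generator.
#' @param nLines number of lines (default 57).
#' @param nSites number of SNP sites per chromosome (default 20000).
#' @param meanDepth mean sequencing depth per cell (reads; default 18).
#' @param epsilon per-read sequencing error probability (default 0.01).
#' @param backgroundHetRate genome-wide Bernoulli heterozygosity rate
#'   outside planted segments (default 0.0041).
#' @param plantedSegments list of \code{list(start, end, rate)} in SNP
#'   indices (1-based, inclusive), non-overlapping, rates above
#'   \code{backgroundHetRate}.
#' @param dupSiteFraction fraction of sites turned into collapsed-paralog
#'   artifacts (doubled depth, ~50/50 counts, low unique mapping).
#' @param missingRate independent per-cell missingness probability
#'   (default 0.25).
#' @param groupSizes integer vector of lines per population group.
#' @param targetFst Balding-Nichols differentiation F in (0,1)
#'   (default 0.15).
#' @param sweepRegions list of \code{list(group, start, end, strength)}
#'   in SNP indices; the focal group's allele frequencies are pushed
#'   toward fixation by \code{strength} in \[0,1\].
#' @param admixtureAlpha mixing proportion for the optional admixed
#'   group (default 0.5).
#' @param admixedGroup index of the group (if any) to draw as an
#'   alpha:(1-alpha) mixture of groups 1 and 2; NA for none.
#' @param siteSpacing bp between consecutive simulated SNPs (default 200).
#' @return a list of class \code{"SimConfig"}.
#' @export
simConfig <- function(seed = 1L, nLines = 57L, nSites = 20000L,
                      meanDepth = 18, epsilon = 0.01,
                      backgroundHetRate = 0.0041,
                      plantedSegments = list(),
                      dupSiteFraction = 0,
                      missingRate = 0.25,
                      groupSizes = c(13L, 14L),
                      targetFst = 0.15,
                      sweepRegions = list(),
                      admixtureAlpha = 0.5,
                      admixedGroup = NA_integer_,
                      siteSpacing = 200L) {
    probs <- c(epsilon = epsilon, backgroundHetRate = backgroundHetRate,
               dupSiteFraction = dupSiteFraction, missingRate = missingRate,
               admixtureAlpha = admixtureAlpha)
    if (any(probs < 0 | probs > 1))
        stop("all probabilities must lie in [0, 1]")
    if (epsilon >= 0.5)
        stop("epsilon >= 0.5 makes the hom/het read model unidentifiable")
    if (length(plantedSegments)) {
        segs <- do.call(rbind, lapply(plantedSegments, function(s)
            c(s$start, s$end, s$rate)))
        if (any(segs[, 1] > segs[, 2]) || any(segs[, 1] < 1) ||
            any(segs[, 2] > nSites))
            stop("planted segments must lie within [1, nSites]")
        o <- order(segs[, 1])
        if (any(segs[o[-1], 1] <= segs[o[-length(o)], 2]))
            stop("planted segments must not overlap")
        if (any(segs[, 3] <= backgroundHetRate))
            stop("planted segment rates must exceed backgroundHetRate")
    }
    cfg <- list(seed = as.integer(seed), nLines = as.integer(nLines),
                nSites = as.integer(nSites), meanDepth = meanDepth,
                epsilon = epsilon, backgroundHetRate = backgroundHetRate,
                plantedSegments = plantedSegments,
                dupSiteFraction = dupSiteFraction,
                missingRate = missingRate,
                groupSizes = as.integer(groupSizes),
                targetFst = targetFst, sweepRegions = sweepRegions,
                admixtureAlpha = admixtureAlpha,
                admixedGroup = admixedGroup,
                siteSpacing = as.integer(siteSpacing))
    class(cfg) <- "SimConfig"
    cfg
}

#' Simulate allele read depths from known genotypes
#'
#' Emulates per-cell read counts under the binomial read model used by the
#' genotype caller: for homozygous cells the minor count is the number of
#' sequencing errors, Binomial(depth, epsilon); for heterozygous cells the
#' two alleles are sampled Binomial(depth, 1/2).  Per-cell depth is
#' Poisson(meanDepth).  A \code{dupSiteFraction} of sites is turned into
#' collapsed-paralog artifacts: doubled depth, ~50/50 counts regardless of
#' the true genotype, and unique-mapping fraction below 0.9.
#'
#' @param truth a \linkS4class{GenotypeCalls} object with no missing
#'   entries (the generating truth).
#' @param cfg a \code{\link{simConfig}} object.
#' @return an \linkS4class{AlleleDepths}; \code{metadata()} records the
#'   seed and the indices of the planted collapsed-paralog sites.
#' @export
simulateReadCounts <- function(truth, cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    if (cfg$epsilon >= 0.5)
        stop("epsilon >= 0.5 makes the hom/het read model unidentifiable")
    g <- genoMatrix(truth)
    if (anyNA(g))
        stop("truth genotypes must have no missing entries")
    if (cfg$meanDepth <= 0)
        stop("meanDepth must be positive")
    set.seed(cfg$seed)
    ns <- nrow(g); nl <- ncol(g)
    depth <- matrix(stats::rpois(ns * nl, cfg$meanDepth), ns, nl)
    ## count2 = reads supporting allele 2: errors for hom1 cells, depth
    ## minus errors for hom2 cells, fair coin for het cells
    p2 <- matrix(cfg$epsilon, ns, nl)
    p2[g == GENO_HET] <- 0.5
    p2[g == GENO_HOM2] <- 1 - cfg$epsilon
    count2 <- matrix(stats::rbinom(ns * nl, depth, p2), ns, nl)
    n1 <- pmax(count2, depth - count2)
    n2 <- pmin(count2, depth - count2)
    majorAllele <- matrix(1L, ns, nl)
    majorAllele[count2 > depth - count2] <- 2L
    uf <- matrix(stats::runif(ns * nl, 0.95, 1), ns, nl)
    dup <- integer(0)
    if (cfg$dupSiteFraction > 0) {
        nDup <- round(cfg$dupSiteFraction * ns)
        dup <- sort(sample.int(ns, nDup))
        if (nDup > 0) {
            d2 <- matrix(stats::rpois(nDup * nl, 2 * cfg$meanDepth), nDup, nl)
            a2 <- matrix(stats::rbinom(nDup * nl, d2, 0.5), nDup, nl)
            n1[dup, ] <- pmax(a2, d2 - a2)
            n2[dup, ] <- pmin(a2, d2 - a2)
            majorAllele[dup, ] <- 1L + (a2 > d2 - a2)
            uf[dup, ] <- matrix(stats::runif(nDup * nl, 0.5, 0.9), nDup, nl)
        }
    }
    ad <- AlleleDepths(n1, n2, uniqueFrac = uf, rowRanges = rowRanges(truth),
                       lineData = colData(truth))
    assays(ad, withDimnames = FALSE)$majorAllele <- majorAllele
    metadata(ad)$seed <- cfg$seed
    metadata(ad)$dupSites <- dup
    ad
}

#' Simulate chromosome-wide heterozygosity profiles
#'
#' Draws the binary line-by-SNP heterozygosity indicator matrix X under
#' the Bernoulli segment model: X_ij ~ Bernoulli(backgroundHetRate)
#' outside planted segments and Bernoulli(segment rate) inside, all cells
#' independent.  An independent per-cell missingness mask is applied at
#' \code{cfg$missingRate}.
#'
#' @param cfg a \code{\link{simConfig}}; \code{plantedSegments} give the
#'   truth intervals.
#' @return \code{list(profile = HetProfile, truth = list(...))}; the truth
#'   records the seed and the planted segment table.
#' @export
simulateHetProfiles <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed)
    nl <- cfg$nLines; ns <- cfg$nSites
    rate <- rep(cfg$backgroundHetRate, ns)
    for (s in cfg$plantedSegments)
        rate[s$start:s$end] <- s$rate
    X <- matrix(stats::rbinom(nl * ns, 1L, rep(rate, each = nl)), nl, ns)
    if (cfg$missingRate > 0)
        X[matrix(stats::runif(nl * ns) < cfg$missingRate, nl, ns)] <- NA_integer_
    prof <- HetProfile(X, positions = seq_len(ns) * cfg$siteSpacing)
    truth <- list(seed = cfg$seed,
                  segments = cfg$plantedSegments,
                  backgroundHetRate = cfg$backgroundHetRate)
    list(profile = prof, truth = truth)
}

## Balding-Nichols draw of subpopulation frequencies around ancestral p
rbaldnich <- function(p, F) {
    if (F <= 0) return(p)
    stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Simulate structured haploid genotypes (Balding-Nichols)
#'
#' Ancestral allele frequencies are Uniform(0.05, 0.95); each group's
#' frequencies are Beta-distributed around them with differentiation
#' parameter F = \code{targetFst} (Balding-Nichols).  Lines are inbred, so
#' genotypes are haploid draws coded as homozygotes (0/2).  Optional
#' planted sweeps push the focal group's frequencies toward fixation;
#' an optional admixed group is drawn from an alpha-mixture of groups 1
#' and 2 plus residual drift.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return \code{list(calls = GenotypeCalls, truth = list(...))}.
#' @export
simulateStructuredGenotypes <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    if (length(cfg$groupSizes) < 2)
        stop("at least 2 groups are required")
    if (cfg$targetFst <= 0 || cfg$targetFst >= 1)
        stop("targetFst must lie in (0, 1)")
    set.seed(cfg$seed)
    ns <- cfg$nSites
    nGroups <- length(cfg$groupSizes)
    pAnc <- stats::runif(ns, 0.05, 0.95)
    freq <- sapply(seq_len(nGroups), function(k) rbaldnich(pAnc, cfg$targetFst))
    if (!is.na(cfg$admixedGroup)) {
        if (cfg$admixedGroup > nGroups || nGroups < 3)
            stop("admixedGroup needs at least 3 groups and a valid index")
        mix <- cfg$admixtureAlpha * freq[, 1] +
            (1 - cfg$admixtureAlpha) * freq[, 2]
        freq[, cfg$admixedGroup] <- rbaldnich(mix, 0.02)  # post-admixture drift
    }
    sweptSites <- rep(FALSE, ns)
    for (s in cfg$sweepRegions) {
        idx <- s$start:s$end
        f <- freq[idx, s$group]
        freq[idx, s$group] <- (1 - s$strength) * f + s$strength * round(f)
        sweptSites[idx] <- TRUE
    }
    groups <- rep(paste0("G", seq_len(nGroups)), cfg$groupSizes)
    nl <- sum(cfg$groupSizes)
    geno <- matrix(NA_integer_, ns, nl)
    col0 <- cumsum(c(0, cfg$groupSizes))
    for (k in seq_len(nGroups)) {
        cols <- (col0[k] + 1):col0[k + 1]
        geno[, cols] <- stats::rbinom(ns * length(cols), 1L, freq[, k]) * GENO_HOM2
    }
    if (cfg$missingRate > 0)
        geno[matrix(stats::runif(ns * nl) < cfg$missingRate, ns, nl)] <- NA_integer_
    pos <- seq_len(ns) * cfg$siteSpacing
    rr <- GRanges("chr1", IRanges(pos, width = 1))
    colnames(geno) <- sprintf("L%02d", seq_len(nl))
    calls <- GenotypeCalls(geno, rowRanges = rr, group = groups)
    metadata(calls)$seed <- cfg$seed
    truth <- list(seed = cfg$seed, freq = freq, ancestral = pAnc,
                  sweptSites = sweptSites, sweepRegions = cfg$sweepRegions,
                  admixedGroup = cfg$admixedGroup,
                  admixedFlag = seq_len(nGroups) %in% cfg$admixedGroup)
    list(calls = calls, truth = truth)
}

#' Neutral coalescent sample with infinite-sites mutations
#'
#' Standard constant-size neutral coalescent (Hudson's algorithm): while k
#' lineages remain, wait Exp(k(k-1)/2) in coalescent time units and merge
#' a random pair.  Mutations fall on branches as a Poisson process with
#' rate theta/2 per unit branch length, so E\[S\] = theta * sum(1/i),
#' i = 1..n-1.  Each mutation is one biallelic site; carriers are the
#' leaves below its branch.
#'
#' @param n sample size (>= 2 haploid sequences).
#' @param theta scaled mutation rate.
#' @param seed optional integer seed.
#' @return \code{list(haplotypes = 0/1 matrix (sites x n), S = #sites)}.
#' @export
simulateCoalescent <- function(n, theta, seed = NULL) {
    if (n < 2) stop("n must be >= 2")
    if (theta < 0) stop("theta must be positive")
    if (!is.null(seed)) set.seed(seed)
    ## active lineages: list of leaf index vectors + accumulated lengths
    leafSets <- as.list(seq_len(n))
    lens <- numeric(n)
    branchSets <- vector("list", 2 * n - 2)
    branchLens <- numeric(2 * n - 2)
    nb <- 0L
    k <- n
    while (k > 1) {
        t <- stats::rexp(1, k * (k - 1) / 2)
        lens <- lens + t
        pair <- sample.int(k, 2)
        for (j in pair) {
            nb <- nb + 1L
            branchSets[[nb]] <- leafSets[[j]]
            branchLens[nb] <- lens[j]
        }
        merged <- c(leafSets[[pair[1]]], leafSets[[pair[2]]])
        keep <- setdiff(seq_len(k), pair)
        leafSets <- c(leafSets[keep], list(merged))
        lens <- c(lens[keep], 0)
        k <- k - 1L
    }
    L <- sum(branchLens)
    S <- stats::rpois(1, theta / 2 * L)
    H <- matrix(0L, S, n)
    if (S > 0) {
        onBranch <- sample.int(nb, S, replace = TRUE, prob = branchLens)
        for (s in seq_len(S))
            H[s, branchSets[[onBranch[s]]]] <- 1L
    }
    list(haplotypes = H, S = S)
}

#' Emulate externally computed XP-CLR window scores
#'
#' The pipeline consumes XP-CLR scores computed by external software;
#' this generator produces a synthetic stand-in score table: null
#' windows draw half-chi-square-like noise, windows inside swept
#' intervals get elevated scores in the direction whose reference group
#' carries the sweep.
#'
#' @param genomeLength chromosome length (bp).
#' @param directions character vector of the two reciprocal comparison
#'   labels (reference-group direction).
#' @param sweeps optional GRanges (or list of \code{list(start, end,
#'   direction)}) of swept bp intervals with the direction carrying the
#'   signal.
#' @param window,step window size and step in bp (default 5000/5000).
#' @param lift score added inside swept windows (default 15).
#' @param seed integer seed.
#' @return data.frame (chrom, start, end, score, direction).
#' @export
simulateXpclrScores <- function(genomeLength, directions = c("AvsB", "BvsA"),
                                sweeps = NULL, window = 5000L, step = 5000L,
                                lift = 15, seed = 1L) {
    set.seed(seed)
    starts <- seq(0, genomeLength - window, by = step)
    out <- do.call(rbind, lapply(directions, function(d) {
        score <- stats::rchisq(length(starts), df = 1)
        if (!is.null(sweeps)) {
            sw <- if (is(sweeps, "GRanges"))
                data.frame(start = start(sweeps), end = end(sweeps),
                           direction = sweeps$direction)
            else do.call(rbind, lapply(sweeps, as.data.frame))
            for (r in which(sw$direction == d)) {
                hit <- starts + window > sw$start[r] & starts < sw$end[r]
                score[hit] <- score[hit] + lift
            }
        }
        data.frame(chrom = "chr1", start = starts, end = starts + window,
                   score = score, direction = d)
    }))
    rownames(out) <- NULL
    out
}

#' Generate gene annotations and gene networks with known truth
#'
#' Places non-overlapping genes along a synthetic chromosome such that the
#' non-genic control mask (everything farther than \code{buffer} bp from
#' any gene) is well separated from every gene, then assembles random gene
#' networks, optionally planting one whose genes coincide with swept
#' regions.
#'
#' @param genomeLength chromosome length in bp.
#' @param nGenes number of genes to place.
#' @param geneLength gene body length in bp (default 3000).
#' @param buffer distance defining the non-genic compartment (default
#'   50000 bp, i.e. controls are >50 kb from genes).
#' @param nNetworks number of random networks (default 20).
#' @param networkSize size range for random networks (default 6:20).
#' @param sweepRegions optional list/GRanges of swept bp intervals; when
#'   \code{plantNetwork} is TRUE the genes overlapping them form the
#'   planted selected network.
#' @param plantNetwork logical; plant a selected network (requires sweeps
#'   covering at least 6 genes).
#' @param seed integer seed.
#' @return list with \code{genes} (GRanges), \code{nongenic} (GRanges
#'   mask), \code{networks} (data.frame network_id, gene_id) and
#'   \code{plantedNetwork} (id or NA).
#' @export
emitAnnotationsAndNetworks <- function(genomeLength, nGenes,
                                       geneLength = 3000L, buffer = 50000L,
                                       nNetworks = 20L, networkSize = 6:20,
                                       sweepRegions = NULL,
                                       plantNetwork = FALSE, seed = 1L) {
    set.seed(seed)
    if (nGenes > 0) {
        slot <- floor(genomeLength / nGenes)
        if (slot < geneLength + 2 * buffer + 2)
            stop("infeasible packing: genome too short for ", nGenes,
                 " genes with ", buffer, " bp buffers")
        jitter <- floor(stats::runif(nGenes) * (slot - geneLength - 1))
        starts <- (seq_len(nGenes) - 1) * slot + jitter + 1
        genes <- GRanges("chr1", IRanges(starts, width = geneLength),
                         gene_id = sprintf("gene%04d", seq_len(nGenes)))
    } else {
        genes <- GRanges()
    }
    chromGr <- GRanges("chr1", IRanges(1, genomeLength))
    if (length(genes)) {
        excl <- GenomicRanges::reduce(genes + buffer)
        nongenic <- GenomicRanges::setdiff(chromGr, excl)
    } else {
        nongenic <- chromGr
    }
    planted <- NA_character_
    netList <- list()
    if (plantNetwork) {
        if (is.null(sweepRegions) || length(sweepRegions) == 0)
            stop("a planted network requires sweep regions")
        if (!is(sweepRegions, "GRanges"))
            sweepRegions <- GRanges("chr1", IRanges(
                sapply(sweepRegions, `[[`, "start"),
                sapply(sweepRegions, `[[`, "end")))
        hit <- unique(S4Vectors::queryHits(
            GenomicRanges::findOverlaps(genes, sweepRegions)))
        if (length(hit) <= 5)
            stop("planted network requires sweeps covering more than 5 genes")
        planted <- "net_planted"
        netList[[planted]] <- genes$gene_id[hit]
    }
    for (i in seq_len(nNetworks)) {
        sz <- sample(networkSize, 1)
        netList[[sprintf("net%03d", i)]] <- sample(genes$gene_id, min(sz, nGenes))
    }
    networks <- data.frame(
        network_id = rep(names(netList), lengths(netList)),
        gene_id = unlist(netList, use.names = FALSE),
        stringsAsFactors = FALSE)
    list(genes = genes, nongenic = nongenic, networks = networks,
         plantedNetwork = planted)
}
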