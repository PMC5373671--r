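library(GenomicRanges)

test_that("region partitioning keeps controls far from genes", {
    genes <- GRanges("chr1", IRanges(seq(100000, 4e6, by = 200000),
                                     width = 3000),
                     gene_id = sprintf("g%02d", 1:20))
    reg <- partitionRegions(genes, 4.2e6, nControls = 200, seed = 1)
    ctrl <- reg[reg$kind == "nongenic"]
    d <- GenomicRanges::distanceToNearest(ctrl, genes)
    expect_true(all(S4Vectors::mcols(d)$distance >= 50000))
    ## genic regions are gene bodies +/- 10 kb
    genic <- reg[reg$kind == "genic"]
    expect_true(all(width(genic) == 23000))
    ## control lengths are drawn from genic lengths
    expect_true(all(width(ctrl) %in% width(genic)))
    ## gene at the chromosome start: flank truncated at 1
    g0 <- GRanges("chr1", IRanges(1, 3000), gene_id = "g0")
    reg0 <- partitionRegions(g0, 3e6, nControls = 10, seed = 1)
    expect_identical(min(start(reg0)), 1L)
    ## a single mid-chromosome gene whose control mask cannot fit any
    ## genic-sized window
    gMid <- GRanges("chr1", IRanges(40000, 43000), gene_id = "g")
    expect_error(partitionRegions(gMid, 100000, nControls = 10, seed = 1),
                 "genome too small")
})

test_that("Weir-Cockerham Fst has the right fixed points and invariances", {
    set.seed(2)
    ## same frequencies, large n: about 0 (possibly slightly negative)
    p <- runif(2000, 0.2, 0.8)
    dosA <- matrix(rbinom(2000 * 40, 1, p), 2000, 40)
    dosB <- matrix(rbinom(2000 * 40, 1, p), 2000, 40)
    f0 <- wcFst(cbind(dosA, dosB), 1:40, 41:80)
    expect_lt(abs(f0), 0.01)
    ## fixed difference: exactly 1
    fix <- cbind(matrix(0L, 100, 8), matrix(1L, 100, 8))
    expect_equal(wcFst(fix, 1:8, 9:16), 1)
    ## allele-label swap and group order leave the estimate unchanged
    dos <- cbind(dosA, dosB)
    dos[1:1000, ] <- 1L - dos[1:1000, ]
    expect_equal(wcFst(dos, 1:40, 41:80), wcFst(dos, 41:80, 1:40))
    expect_equal(wcFst(cbind(dosA, dosB), 1:40, 41:80),
                 wcFst(1L - cbind(dosA, dosB), 1:40, 41:80))
})

test_that("empirical p-values use the pseudo-counted rank and are uniform", {
    ctrl <- seq_len(999)
    expect_equal(empiricalPvalue(1000, ctrl, "upper"), 1 / 1000)
    expect_equal(empiricalPvalue(500, ctrl, "upper"), 0.501)
    expect_equal(empiricalPvalue(0, ctrl, "lower"), 1 / 1000)
    expect_error(empiricalPvalue(1, 1:50, "upper"), "at least")
    ## exchangeable genes and controls: uniform p over simulations
    set.seed(3)
    ps <- replicate(10000, empiricalPvalue(rnorm(1), rnorm(999), "upper"))
    expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("external window scores are assigned to regions by max overlap", {
    regions <- GRanges("chr1", IRanges(c(1000, 60000), width = 5000),
                       region_id = c("r1", "r2"), kind = "genic")
    sc <- data.frame(chrom = "chr1",
                     start = c(0, 2000, 4000), end = c(2000, 4000, 6000),
                     score = c(1, 7, 3), direction = "AvsB")
    out <- importXpclr(sc, regions)
    expect_equal(out$xpclr_AvsB, c(7, NA))
    bad <- sc; bad$score[2] <- NA
    expect_error(importXpclr(bad, regions), "lines: 2")
})

test_that("the three-statistic candidate rule is conjunctive", {
    base <- data.frame(region_id = "r", fstP = 0.01, xpclrP1 = 0.01,
                       xpclrP2 = 0.5, d1 = -1.2, d2 = 0.5,
                       dP1 = 0.01, dP2 = 0.6)
    expect_true(callDsCandidates(base)$candidate)
    noXp <- base; noXp$xpclrP1 <- 0.2
    expect_false(callDsCandidates(noXp)$candidate)
    posD <- base; posD$d1 <- 1.2      # significant but positive D
    expect_false(callDsCandidates(posD)$candidate)
    ## missing statistics exclude the region and are counted
    withNa <- rbind(base, base)
    withNa$fstP[2] <- NA
    out <- callDsCandidates(withNa)
    expect_identical(nrow(out), 1L)
    expect_identical(attr(out, "nExcluded"), 1L)
})

test_that("expected false positives scale the control pass fraction", {
    set.seed(4)
    n <- 2000
    ctrl <- data.frame(region_id = sprintf("c%04d", 1:n),
                       fstP = runif(n), xpclrP1 = runif(n),
                       xpclrP2 = runif(n), d1 = rnorm(n), d2 = rnorm(n),
                       dP1 = runif(n), dP2 = runif(n))
    out <- expectedFalsePositives(ctrl, 39423)
    ## independent uniforms: pass fraction near
    ## 0.05 * (1-(1-0.05)^2) * P(sig negative D in >= 1 group)
    expect_lt(out$fraction, 0.0015)
    expect_equal(out$expected, out$fraction * 39423)
    none <- ctrl; none$fstP <- 1
    expect_equal(expectedFalsePositives(none, 100)$expected, 0)
    ## the worked scaling: fraction 0.00134 over 39423 genes ~ 53
    expect_equal(0.00134 * 39423, 52.8, tolerance = 0.01)
})

test_that("region statistics apply the analyzability rules", {
    cfg <- simConfig(seed = 5, nSites = 4000, groupSizes = c(10L, 10L),
                     targetFst = 0.1, missingRate = 0.1)
    gg <- simulateStructuredGenotypes(cfg)
    genomeLength <- 4001 * 200
    genes <- GRanges("chr1", IRanges(c(100000, 300000, 500000), width = 3000),
                     gene_id = c("gA", "gB", "gC"))
    reg <- partitionRegions(genes, genomeLength, flank = 10000,
                            controlDistance = 20000, nControls = 50,
                            seed = 6)
    rs <- regionStats(gg$calls, reg, "G1", "G2")
    expect_true(all(is.na(rs$fst[rs$nSnps <= 7])))
    ok <- !is.na(rs$fst)
    expect_true(all(rs$missA[ok] <= 0.3 & rs$missB[ok] <= 0.3))
    expect_true(all(rs$fst[ok] <= 1))
})

test_that("swept genes are enriched among differential-selection candidates", {
    nSites <- 16000; spacing <- 200
    genomeLength <- (nSites + 1) * spacing
    ann <- emitAnnotationsAndNetworks(genomeLength, nGenes = 60,
                                      geneLength = 3000, buffer = 10000,
                                      nNetworks = 5, seed = 7)
    pick <- sort(sample(60, 10))
    sg <- ann$genes[pick]
    sweeps <- lapply(seq_along(sg), function(i) list(
        group = 1,
        start = max(1, (start(sg)[i] - 12000) %/% spacing),
        end = min(nSites, (end(sg)[i] + 12000) %/% spacing),
        strength = 0.95))
    cfg <- simConfig(seed = 7, nSites = nSites, groupSizes = c(13L, 14L),
                     targetFst = 0.15, sweepRegions = sweeps,
                     missingRate = 0.2)
    gg <- simulateStructuredGenotypes(cfg)
    regions <- partitionRegions(ann$genes, genomeLength, flank = 10000,
                                controlDistance = 10000, nControls = 300,
                                seed = 8)
    rs <- regionStats(gg$calls, regions, "G1", "G2")
    ctrl <- rs$kind == "nongenic" & !is.na(rs$fst)
    xp <- importXpclr(simulateXpclrScores(
        genomeLength, directions = c("G1", "G2"),
        sweeps = lapply(seq_along(sg), function(i) list(
            start = start(sg)[i] - 12000, end = end(sg)[i] + 12000,
            direction = "G1")), seed = 9), regions)
    stats <- data.frame(
        region_id = rs$region_id, kind = rs$kind,
        fstP = empiricalPvalue(rs$fst, rs$fst[ctrl], "upper",
                               minControls = 50),
        xpclrP1 = empiricalPvalue(xp$xpclr_G1, xp$xpclr_G1[which(ctrl)],
                                  "upper", minControls = 50),
        xpclrP2 = empiricalPvalue(xp$xpclr_G2, xp$xpclr_G2[which(ctrl)],
                                  "upper", minControls = 50),
        d1 = rs$dA, d2 = rs$dB,
        dP1 = empiricalPvalue(rs$dA, rs$dA[ctrl], "lower",
                              minControls = 50),
        dP2 = empiricalPvalue(rs$dB, rs$dB[ctrl], "lower",
                              minControls = 50))
    cand <- callDsCandidates(stats[stats$kind == "genic", ])
    swept <- cand$region_id %in% ann$genes$gene_id[pick]
    tab <- table(factor(swept, c(FALSE, TRUE)),
                 factor(cand$candidate, c(FALSE, TRUE)))
    expect_lt(fisher.test(tab, alternative = "greater")$p.value, 0.01)
})
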