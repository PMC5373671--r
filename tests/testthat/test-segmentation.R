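test_that("dynamic program equals exhaustive enumeration on random profiles", {
    set.seed(1)
    checked <- 0
    while (checked < 200) {
        n <- sample(4:14, 1); L <- sample(1:6, 1)
        prof <- randomProfile(n, L)
        h <- colSums(prof@X == 1L, na.rm = TRUE)
        m <- colSums(!is.na(prof@X))
        Kmax <- min(4L, n)
        seg <- segmentChromosome(prof, Kmax = Kmax, method = "suffix")
        for (K in seq_len(Kmax)) {
            oracle <- bruteSegment(h, m, K)
            expect_lt(abs(oracle$logLik - seg$logLik[K]), 1e-9)
            expect_identical(as.integer(seg$segments[[K]]$end[-K]),
                             as.integer(oracle$breakpoints))
        }
        checked <- checked + 1
    }
})

test_that("candidate pruning does not change the optimum", {
    set.seed(2)
    for (rep in 1:10) {
        n <- sample(300:800, 1)
        rate <- rep(0.01, n)
        if (rep %% 2) rate[101:140] <- 0.3
        X <- matrix(rbinom(6 * n, 1, rep(rate, each = 6)), 6, n)
        X[runif(6 * n) < 0.2] <- NA
        bad <- colSums(!is.na(X)) == 0; X[1, bad] <- 0L
        p <- HetProfile(X)
        a <- segmentChromosome(p, Kmax = 8, method = "suffix")
        b <- segmentChromosome(p, Kmax = 8, method = "pruned")
        expect_lt(max(abs(a$logLik - b$logLik)), 1e-8)
    }
})

test_that("degenerate profiles segment as expected", {
    ## all-zero profile: any K has the same likelihood, all rates 0
    prof0 <- HetProfile(matrix(0L, 3, 10))
    seg0 <- segmentChromosome(prof0, Kmax = 4)
    expect_true(all(abs(seg0$logLik - seg0$logLik[1]) < 1e-12))
    expect_true(all(seg0$segments[[4]]$rate == 0))
    ## perfect split 000111: K = 2 puts the breakpoint at 3|4
    prof <- HetProfile(matrix(c(0L, 0L, 0L, 1L, 1L, 1L), 1))
    seg <- segmentChromosome(prof, Kmax = 2)
    expect_identical(seg$segments[[2]]$end, c(3L, 6L))
    expect_equal(seg$segments[[2]]$rate, c(0, 1))
    ## all-missing columns are rejected
    Xm <- matrix(NA_integer_, 2, 4); Xm[1, c(1, 2, 4)] <- 0L
    expect_error(segmentChromosome(HetProfile(Xm), Kmax = 2),
                 "all-missing")
    ## log-likelihood is non-decreasing in K
    set.seed(3)
    prof2 <- randomProfile(40, 5)
    seg2 <- segmentChromosome(prof2, Kmax = 10)
    expect_true(all(diff(seg2$logLik) > -1e-9))
})

test_that("segmentation is invariant to line ordering", {
    set.seed(4)
    prof <- randomProfile(60, 8, rate = 0.1)
    perm <- sample(8)
    profPerm <- HetProfile(prof@X[perm, ], prof@positions, prof@chrom)
    a <- segmentChromosome(prof, Kmax = 6)
    b <- segmentChromosome(profPerm, Kmax = 6)
    expect_equal(a$logLik, b$logLik)
    expect_identical(a$segments[[4]], b$segments[[4]])
})

test_that("model selection finds one segment in noise and three around a planted segment", {
    expect_identical(selectK(segmentChromosome(
        HetProfile(matrix(0L, 2, 1)), Kmax = 1)), 1L)
    nullHits <- 0
    for (i in 1:100) {
        cfg <- simConfig(seed = 500 + i, nLines = 57, nSites = 400,
                         backgroundHetRate = 0.004, missingRate = 0.25)
        prof <- simulateHetProfiles(cfg)$profile
        if (selectK(segmentChromosome(prof, Kmax = 10)) == 1L)
            nullHits <- nullHits + 1
    }
    expect_gte(nullHits, 95)
    plantedHits <- 0
    for (i in 1:50) {
        cfg <- simConfig(seed = 900 + i, nLines = 57, nSites = 200,
                         backgroundHetRate = 0.004, missingRate = 0,
                         plantedSegments = list(list(start = 86, end = 115,
                                                     rate = 0.4)))
        prof <- simulateHetProfiles(cfg)$profile
        if (selectK(segmentChromosome(prof, Kmax = 8)) == 3L)
            plantedHits <- plantedHits + 1
    }
    expect_gte(plantedHits, 45)
})

test_that("exact segment test equals independent tail summation", {
    expect_equal(exactSegmentTest(0, 100, 0.01), 1)
    expect_equal(exactSegmentTest(5, 100, 0.05),
                 1 - pbinom(4, 100, 0.05), tolerance = 1e-12)
    expect_equal(exactSegmentTest(5, 100, 0.05),
                 binomTailOracle(5, 100, 0.05), tolerance = 1e-12)
    expect_equal(exactSegmentTest(12, 570, 0.0041),
                 binomTailOracle(12, 570, 0.0041), tolerance = 1e-15)
    expect_error(exactSegmentTest(1, 10, 0), "strictly inside")
    expect_error(exactSegmentTest(1, 0, 0.1), "at least one")
})

test_that("BH adjustment matches hand computation", {
    expect_equal(bhAdjust(0.01), 0.01)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
})

test_that("merge and filter rules follow the published post-processing", {
    seg <- function(start, end, het, nonmiss, sig)
        data.frame(start = start, end = end, nSnps = end - start + 1L,
                   het = het, nonmissing = nonmiss, significant = sig)
    ## S,S,N -> S-merged + N
    d <- rbind(seg(1, 10, 50, 100, TRUE), seg(11, 20, 60, 100, TRUE),
               seg(21, 40, 1, 200, FALSE))
    out <- mergeAndFilter(d, pg = 0.05)
    expect_identical(nrow(out), 2L)
    expect_equal(out$nSnps[1], 20)
    expect_equal(out$het[1], 110)
    ## a sub-5-SNP segment between same-status neighbors vanishes and
    ## the neighbors merge
    d2 <- rbind(seg(1, 10, 2, 500, FALSE), seg(11, 13, 40, 60, TRUE),
                seg(14, 25, 3, 600, FALSE))
    out2 <- mergeAndFilter(d2, pg = 0.004)
    expect_identical(nrow(out2), 1L)
    expect_false(out2$significant[1])
    expect_equal(out2$nSnps[1], 22)
    ## 4-SNP segments are excluded outright
    d3 <- seg(1, 4, 10, 40, TRUE)
    expect_identical(nrow(mergeAndFilter(d3, pg = 0.004)), 0L)
    ## merged segments are re-tested on pooled counts
    d4 <- rbind(seg(1, 10, 30, 500, TRUE), seg(11, 20, 30, 500, TRUE))
    out4 <- mergeAndFilter(d4, pg = 0.004)
    expect_equal(out4$p, exactSegmentTest(60, 1000, 0.004))
})

test_that("null heterozygosity profiles yield few significant segments", {
    ## genome-scale null: fraction of significant final segments within
    ## the nominal FDR plus Monte-Carlo error
    fracs <- vapply(1:12, function(i) {
        cfg <- simConfig(seed = 1200 + i, nLines = 57, nSites = 20000,
                         backgroundHetRate = 0.004, missingRate = 0.25)
        prof <- simulateHetProfiles(cfg)$profile
        hs <- hetSegments(prof, Kmax = 15)
        mean(hs$segments$significant)
    }, numeric(1))
    se <- sd(fracs) / sqrt(length(fracs))
    expect_lte(mean(fracs), 0.05 + 2 * max(se, 1e-3))
})

test_that("planted heterozygous segments are recovered with low FDR", {
    planted <- list(list(start = 301, end = 315, rate = 0.15),
                    list(start = 901, end = 920, rate = 0.3),
                    list(start = 1501, end = 1512, rate = 0.1))
    recall <- c(); fdr <- c()
    for (i in 1:8) {
        cfg <- simConfig(seed = 1400 + i, nLines = 57, nSites = 2000,
                         backgroundHetRate = 0.004, missingRate = 0.25,
                         plantedSegments = planted)
        hs <- hetSegments(simulateHetProfiles(cfg)$profile, Kmax = 15)
        sig <- hs$segments[hs$segments$significant, , drop = FALSE]
        hit <- vapply(planted, function(s)
            any(sig$start <= s$end & sig$end >= s$start), logical(1))
        fp <- if (nrow(sig)) mean(!vapply(seq_len(nrow(sig)), function(r)
            any(vapply(planted, function(s)
                sig$start[r] <= s$end & sig$end[r] >= s$start,
                logical(1))), logical(1))) else 0
        recall <- c(recall, mean(hit)); fdr <- c(fdr, fp)
    }
    expect_gte(mean(recall), 0.9)
    expect_lte(mean(fdr), 0.1)
})

test_that("doubled-haploid validation classifies artifact segments", {
    segs <- data.frame(start = c(1, 11), end = c(10, 20),
                       nSnps = c(10L, 10L), het = c(30, 30),
                       nonmissing = c(500, 500),
                       significant = c(TRUE, TRUE),
                       startBp = c(100, 1100), endBp = c(1000, 2000))
    ## DH panel heterozygous inside segment 1 only
    Xdh <- matrix(0L, 10, 20)
    Xdh[, 1:10][runif(100) < 0.5] <- 1L
    set.seed(5); Xdh <- matrix(0L, 10, 20)
    Xdh[, 1:10] <- rbinom(100, 1, 0.5)
    dh <- HetProfile(Xdh, positions = seq(100, 2000, by = 100))
    out <- validateInDh(segs, dh)
    expect_identical(out$class, c(2L, 1L))
    ## all-zero DH profile: everything class 1
    dh0 <- HetProfile(matrix(0L, 10, 20),
                      positions = seq(100, 2000, by = 100))
    out0 <- validateInDh(segs, dh0)
    expect_true(all(out0$class == 1L))
    ## too few DH SNPs: untestable
    dhSmall <- HetProfile(matrix(0L, 10, 4),
                          positions = c(150, 250, 350, 450))
    outS <- validateInDh(segs[1, ], dhSmall)
    expect_true(is.na(outS$class[1]))
})

test_that("contributor counts separate single-line and shared segments", {
    X <- matrix(0L, 5, 30)
    X[1, 1:10] <- 1L              # one line only
    X[, 21:30] <- 1L              # all lines
    prof <- HetProfile(X, positions = seq_len(30) * 100)
    segs <- data.frame(startBp = c(100, 2100), endBp = c(1000, 3000))
    cd <- contributorDistribution(segs, prof)
    expect_identical(cd$contributors, c(1L, 5L))
})

test_that("deleterious enrichment reproduces the hand chi-square", {
    ## equal proportions: statistic 0
    eq <- deleteriousEnrichment(rep(c(TRUE, FALSE), each = 100),
                                rep(c(TRUE, FALSE), 100))
    expect_equal(eq$statistic, 0)
    ## ((10,90),(20,80)) -> 3.92 on 1 df
    inSeg <- rep(c(FALSE, TRUE), each = 100)
    del <- c(rep(TRUE, 10), rep(FALSE, 90), rep(TRUE, 20), rep(FALSE, 80))
    out <- deleteriousEnrichment(inSeg, del)
    expect_equal(out$statistic, 3.9216, tolerance = 1e-4)
    expect_identical(out$df, 1L)
    ## power: planted 2x enrichment on 1e5 variants
    set.seed(6)
    inSeg2 <- rep(c(FALSE, TRUE), each = 5e4)
    del2 <- c(rbinom(5e4, 1, 0.05), rbinom(5e4, 1, 0.10)) == 1
    expect_lt(deleteriousEnrichment(inSeg2, del2)$p.value, 1e-6)
    ## zero margin: inapplicable
    zm <- deleteriousEnrichment(rep(TRUE, 10), rep(c(TRUE, FALSE), 5))
    expect_true(is.na(zm$statistic))
})
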