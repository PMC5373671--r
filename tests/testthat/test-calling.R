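test_that("likelihood-ratio caller reproduces direct binomial computation", {
    cfg <- callerConfig()
    expect_identical(callGenotype(30, 0, cfg), "hom")
    expect_identical(callGenotype(15, 15, cfg), "het")
    ## (28, 2): LRT from independent log-pmf computation
    llHom <- dbinom(2, 30, 0.01, log = TRUE)
    llHet <- dbinom(2, 30, 0.5, log = TRUE)
    lrt <- 2 * (llHom - llHet)
    expect_gt(lrt, 3.841)
    expect_equal(lrt, 22.6, tolerance = 0.01)
    expect_identical(callGenotype(28, 2, cfg), "hom")
    ## below min depth or non-significant LRT: missing
    expect_true(is.na(callGenotype(3, 2, cfg)))
    expect_true(is.na(callGenotype(5, 1, cfg)))  # depth 6, LRT ~ 1.0
    expect_error(callGenotype(-1, 0, cfg), "negative")
    expect_error(callGenotype(2, 5, cfg), "n1 must be")
})

test_that("depth and mapping filters mask cells and drop sites", {
    n1 <- matrix(18L, 3, 4); n2 <- matrix(0L, 3, 4)
    n1[2, ] <- 29L                     # site 2: mean depth 29 > 28
    uf <- matrix(0.99, 3, 4)
    uf[3, 1] <- 0.5                    # site 3, line 1: multimapper
    ad <- AlleleDepths(n1, n2, uniqueFrac = uf)
    geno <- matrix(0L, 3, 4)
    out <- filterDepthAndMapping(ad, geno, callerConfig())
    expect_identical(which(out$dropDepth), 2L)
    expect_true(is.na(out$geno[3, 1]))            # masked for mapping
    expect_false(any(out$dropMultimap))           # masked cell was not het
    geno[3, 1] <- 1L
    out2 <- filterDepthAndMapping(ad, geno, callerConfig())
    expect_identical(which(out2$dropMultimap), 3L)  # ambiguous AND het
    ## clean input: nothing masked
    adc <- AlleleDepths(matrix(18L, 2, 3), matrix(0L, 2, 3))
    outc <- filterDepthAndMapping(adc, matrix(0L, 2, 3), callerConfig())
    expect_false(any(is.na(outc$geno)))
    expect_false(any(outc$dropDepth | outc$dropMultimap))
})

test_that("error-count filters flag improbable error counts", {
    ## one cell with 10 errors in 20 reads at eps = 0.01
    tail10 <- binomTailOracle(10, 20, 0.01)
    expect_lt(tail10, 1e-13)
    n1 <- matrix(c(20L, 10L), 1, 2); n2 <- matrix(c(0L, 10L), 1, 2)
    ad <- AlleleDepths(matrix(c(20L, 10L), 1, 2), matrix(c(0L, 10L), 1, 2))
    ## force a hom call in cell 2 so its minor count counts as errors
    geno <- matrix(c(0L, 0L), 1, 2)
    out <- filterErrorCounts(ad, geno, callerConfig())
    expect_true(out$dropBinomial[1])
    ## all error counts zero: retained
    ad0 <- AlleleDepths(matrix(18L, 2, 5), matrix(0L, 2, 5))
    out0 <- filterErrorCounts(ad0, matrix(0L, 2, 5), callerConfig())
    expect_false(any(out0$dropBinomial | out0$dropPoisson))
    ## literal reading drops the opposite tail
    outLit <- filterErrorCounts(ad0, matrix(0L, 2, 5),
                                callerConfig(literalErrorRule = TRUE))
    expect_true(all(outLit$dropBinomial))
})

test_that("Poisson KS error filter rejects at most alpha on Poisson data", {
    set.seed(1)
    nrej <- 0; nsites <- 600
    for (i in seq_len(nsites)) {
        err <- pmin(rpois(40, 2), 8L)
        depth <- pmax(err + 10L, 18L)
        ad <- AlleleDepths(matrix(depth - err, 1), matrix(err, 1))
        out <- filterErrorCounts(ad, matrix(0L, 1, 40),
                                 callerConfig(epsilon = 0.15))
        if (out$dropPoisson[1]) nrej <- nrej + 1
    }
    ## the discrete-adapted KS is conservative: level at or below alpha
    expect_lte(nrej / nsites, 0.05 + 2 * sqrt(0.05 * 0.95 / nsites))
})

test_that("het-context rules mask near indels and drop unsupported hets", {
    geno <- rbind(c(1L, 0L, 0L),     # het without hom2 support
                  c(1L, 0L, 2L),     # het with both homs
                  c(0L, 0L, 0L))     # monomorphic
    pos <- c(1000, 1400, 1600)
    out <- filterHetContext(geno, pos, indelPos = NULL, callerConfig())
    expect_identical(which(out$dropHetRule), 1L)
    expect_identical(which(out$dropMonomorphic), 3L)
    ## indel at 1000: het at 1400 masked (<500 bp), het at 1600 kept
    geno2 <- rbind(c(1L, 0L, 2L), c(1L, 0L, 2L))
    out2 <- filterHetContext(geno2, c(1400, 1600), indelPos = 1000,
                             callerConfig())
    expect_true(is.na(out2$geno[1, 1]))
    expect_identical(out2$geno[2, 1], 1L)
})

test_that("filter fates partition sites and are idempotent", {
    truth <- GenotypeCalls(matrix(sample(c(0L, 2L), 400 * 20, TRUE),
                                  400, 20))
    cfg <- simConfig(seed = 11, dupSiteFraction = 0.08)
    ad <- simulateReadCounts(truth, cfg)
    res <- callAndFilter(ad, callerConfig())
    expect_identical(nrow(res$report), 400L)
    expect_identical(sum(res$fateCounts), 400L)
    expect_identical(sum(res$report$fate == "retained"),
                     nrow(genoMatrix(res$calls)))
    res2 <- callAndFilter(ad, callerConfig())
    expect_identical(res$report, res2$report)
    ## >= 90% of collapsed-paralog sites removed
    dup <- S4Vectors::metadata(ad)$dupSites
    expect_gte(mean(res$report$fate[dup] != "retained"), 0.9)
})

test_that("per-line heterozygosity rate uses the alternative-allele denominator", {
    g <- cbind(c(rep(1L, 2), rep(2L, 98)),   # 2 het / (2 het + 98 hom-alt)
               rep(0L, 100),                 # all hom-ref: undefined
               c(rep(1L, 10), rep(NA, 90)))  # missing excluded
    gm <- GenotypeCalls(g)
    r <- perLineHetRate(gm)
    expect_equal(unname(r[1]), 0.02)
    expect_true(is.na(r[2]))
    expect_equal(unname(r[3]), 1)
})

test_that("concordance rates behave at the boundaries and recover planted error", {
    a <- matrix(0L, 50, 4); b <- a
    expect_equal(concordanceReport(a, b)$homDiscrepancy, 0)
    aa <- matrix(1L, 50, 4); bb <- matrix(0L, 50, 4)
    expect_equal(concordanceReport(aa, bb)$hetFalsePositive, 1)
    ## planted 1% hom discordance on 1e4 cells
    set.seed(2)
    a <- matrix(sample(c(0L, 2L), 1e4, TRUE), 2500, 4)
    b <- a
    flip <- sample(length(a), 100)
    b[flip] <- 2L - b[flip]
    rate <- concordanceReport(a, b)$homDiscrepancy
    expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / 1e4))
    expect_error(concordanceReport(matrix(NA_integer_, 2, 2),
                                   matrix(NA_integer_, 2, 2)), "shared")
})

test_that("het-rate distribution comparison is a calibrated two-sample KS", {
    same <- compareHetDistributions(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$statistic, 0)
    disj <- compareHetDistributions(1:5, 11:15)
    expect_equal(disj$statistic, 1)
    set.seed(3)
    rej <- mean(replicate(1000, {
        compareHetDistributions(rnorm(40), rnorm(40))$p.value < 0.05
    }))
    expect_lt(abs(rej - 0.05), 0.025)
})

test_that("hom miscall rate is small and het misses shrink with depth", {
    ## simulated counts at depth 18, eps 0.01: hom miscall < 0.1%
    truthHom <- GenotypeCalls(matrix(0L, 2000, 25))
    ad <- simulateReadCounts(truthHom, simConfig(seed = 5, meanDepth = 18))
    g <- inbredscan:::callMatrix(ad, callerConfig())
    expect_lt(mean(g == 1L, na.rm = TRUE), 0.001)
    fn <- vapply(c(6, 12, 18, 30), function(d) {
        truthHet <- GenotypeCalls(matrix(1L, 1500, 20))
        adh <- simulateReadCounts(truthHet, simConfig(seed = 6,
                                                      meanDepth = d))
        gh <- inbredscan:::callMatrix(adh, callerConfig())
        mean(is.na(gh) | gh != 1L)
    }, numeric(1))
    expect_true(all(diff(fn) <= 0))
})
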