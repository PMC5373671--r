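#' Pairwise Weir-Cockerham Fst matrix between groups
#'
#' Multi-locus haploid Weir-Cockerham Fst for every pair of groups,
#' optionally with empirical p-values from per-site permutations of the
#' group labels.  Singleton groups are skipped with a warning.
#'
#' @param x a \linkS4class{GenotypeCalls} with group labels, or a dosage
#'   matrix with \code{groups} supplied.
#' @param groups per-line group labels (default from the object).
#' @return symmetric numeric matrix of Fst values (diagonal 0).
#' @export
pairwiseFstMatrix <- function(x, groups = NULL) {
    dos <- asDosage(x)
    if (is.null(groups)) groups <- lineGroups(x)
    stopifnot(length(groups) == ncol(dos))
    tab <- table(groups)
    ok <- names(tab)[tab >= 2]
    if (length(ok) < length(tab))
        warning("skipping singleton groups: ",
                paste(setdiff(names(tab), ok), collapse = ", "))
    m <- matrix(NA_real_, length(ok), length(ok), dimnames = list(ok, ok))
    diag(m) <- 0
    if (length(ok) > 1) {
        for (i in seq_len(length(ok) - 1)) for (j in (i + 1):length(ok)) {
            f <- wcFst(dos, which(groups == ok[i]), which(groups == ok[j]))
            m[i, j] <- m[j, i] <- f
        }
    }
    m
}

#' Three-population admixture test (f3)
#'
#' Patterson's f3(C; A, B): the mean over SNPs of
#' (c - a)(c - b) - c(1 - c)/(n_C - 1), where a, b, c are the sample
#' allele frequencies in the two sources and the target and the last
#' term removes the bias from the target's finite (haploid) sample size.
#' A significantly negative f3 indicates that C derives from an
#' admixture of populations related to A and B.  The standard error is a
#' leave-one-block-out jackknife over consecutive SNP blocks (default
#' 25 SNPs), and Z = f3 / SE, with Z < -1.64 significant at the 5%
#' level.
#'
#' @param x a \linkS4class{GenotypeCalls} or dosage matrix.
#' @param target,sourceA,sourceB group labels or column index vectors.
#' @param blockSize jackknife block length in SNPs (default 25).
#' @param minBlocks minimum number of blocks (default 100).
#' @return list(f3, se, z, significant, nSnps, nBlocks).
#' @export
f3Test <- function(x, target, sourceA, sourceB, blockSize = 25L,
                   minBlocks = 100L) {
    dos <- asDosage(x)
    colsOf <- function(g) if (is.character(g) && length(g) == 1)
        which(lineGroups(x) == g) else g
    cc <- colsOf(target); ca <- colsOf(sourceA); cb <- colsOf(sourceB)
    if (length(cc) < 2 || length(ca) < 2 || length(cb) < 2)
        stop("all three groups need at least 2 lines")
    freq <- function(cols) {
        sub <- dos[, cols, drop = FALSE]
        n <- rowSums(!is.na(sub))
        k <- rowSums(sub == 1L, na.rm = TRUE)
        list(p = ifelse(n > 0, k / n, NA), n = n)
    }
    fa <- freq(ca); fb <- freq(cb); fc <- freq(cc)
    poly <- (fa$p > 0 & fa$p < 1) | (fb$p > 0 & fb$p < 1) |
        (fc$p > 0 & fc$p < 1)
    use <- which(fc$n >= 2 & fa$n >= 1 & fb$n >= 1 & poly &
                 !is.na(fa$p) & !is.na(fb$p) & !is.na(fc$p))
    a <- fa$p[use]; b <- fb$p[use]; cfr <- fc$p[use]; nc <- fc$n[use]
    v <- (cfr - a) * (cfr - b) - cfr * (1 - cfr) / (nc - 1)
    nb <- floor(length(v) / blockSize)
    if (nb < minBlocks)
        stop("too few jackknife blocks (", nb, " < ", minBlocks, ")")
    v <- v[seq_len(nb * blockSize)]
    f3 <- mean(v)
    blk <- rep(seq_len(nb), each = blockSize)
    blockSums <- tapply(v, blk, sum)
    total <- sum(v); nv <- length(v)
    loo <- (total - blockSums) / (nv - blockSize)
    se <- sqrt((nb - 1) / nb * sum((loo - mean(loo))^2))
    z <- f3 / se
    list(f3 = f3, se = se, z = z, significant = z < -1.64,
         nSnps = nv, nBlocks = nb)
}
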