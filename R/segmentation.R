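#' @useDynLib inbredscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## pooled per-column counts of a HetProfile
profileCounts <- function(profile) {
    X <- profile@X
    h <- colSums(X == 1L, na.rm = TRUE)
    m <- colSums(!is.na(X))
    if (any(m == 0))
        stop("all-missing SNP columns are not allowed; drop them first")
    list(h = as.integer(h), m = as.integer(m))
}

#' Joint Bernoulli segmentation of a heterozygosity profile
#'
#' Splits the SNP columns of a chromosome into K contiguous segments, for
#' every K up to \code{Kmax}, maximizing the joint Bernoulli
#' log-likelihood.  A segment pools all non-missing cells across lines
#' and its rate MLE is \#het / \#non-missing.  The optimum is found by
#' the classical segment-cost dynamic program, made fast by tabulating
#' x log x over the integer pooled counts.  Ties are broken by the
#' leftmost breakpoints.
#'
#' @param profile a \linkS4class{HetProfile}.
#' @param Kmax largest number of segments to fit (default
#'   \code{min(nSnps, 50)}).
#' @param tol tie tolerance for breakpoint reconstruction.
#' @param method \code{"suffix"} = plain suffix DP (exact leftmost-tie
#'   reconstruction), \code{"pruned"} = prefix DP with candidate
#'   pruning (identical optimum, much faster on long profiles),
#'   \code{"auto"} = suffix up to 3000 SNPs, pruned beyond.
#' @return an object of class \code{"BernoulliSegmentation"}: list with
#'   \code{logLik} (optimal log-likelihood per K), \code{segments}
#'   (per-K data.frame of start, end, nSnps, het, nonmissing, rate) and
#'   the pooled counts.
#' @export
segmentChromosome <- function(profile, Kmax = NULL, tol = 1e-9,
                              method = c("auto", "suffix", "pruned")) {
    method <- match.arg(method)
    cnt <- profileCounts(profile)
    n <- length(cnt$h)
    if (n < 1) stop("profile has no SNPs")
    if (is.null(Kmax)) Kmax <- min(n, 50L)
    if (Kmax > n) stop("Kmax cannot exceed the number of SNPs")
    suffix <- method == "suffix" || (method == "auto" && n <= 3000)
    if (suffix) {
        E <- dp_suffix_exact(cnt$h, cnt$m, Kmax)
        logLik <- -E[, 1]
        segs <- lapply(seq_len(Kmax), function(K)
            reconstructSegments(cnt$h, cnt$m, E, K, tol))
    } else {
        D <- dp_prefix_pruned(cnt$h, cnt$m, Kmax)
        logLik <- -D[, n]
        segs <- lapply(seq_len(Kmax), function(K)
            reconstructSegmentsPrefix(cnt$h, cnt$m, D, K, tol))
    }
    structure(list(logLik = logLik, segments = segs, n = n,
                   h = cnt$h, m = cnt$m,
                   positions = profile@positions, chrom = profile@chrom,
                   Kmax = Kmax),
              class = "BernoulliSegmentation")
}

## front-to-back reconstruction with leftmost tie-break: at each step the
## smallest end t whose cost(i, t) + E(k-1, t+1) matches E(k, i) (within
## tol) ends the current segment.
reconstructSegments <- function(h, m, E, K, tol = 1e-9) {
    n <- length(h)
    bounds <- integer(0)
    i <- 1L
    if (K > 1) {
        for (k in K:2) {
            cand <- i:(n - k + 1L)
            costs <- seg_cost_row(h, m, i)[cand - i + 1L]
            val <- costs + E[k - 1L, cand + 1L]   # E(k-1, t+1)
            target <- E[k, i]
            t <- cand[which(val <= target + tol)[1]]
            bounds <- c(bounds, t)
            i <- t + 1L
        }
    }
    starts <- c(1L, bounds + 1L)
    ends <- c(bounds, n)
    segTable(h, m, starts, ends)
}

## back-to-front reconstruction on the pruned prefix DP; at each step the
## smallest split t whose D(k-1, t) + cost(t+1, j) matches D(k, j)
## (within tol) starts the current segment.  Equivalent to the suffix
## reconstruction except in exact ties.
reconstructSegmentsPrefix <- function(h, m, D, K, tol = 1e-9) {
    n <- length(h)
    bounds <- integer(0)
    j <- n
    if (K > 1) {
        for (k in K:2) {
            cand <- (k - 1L):(j - 1L)
            costs <- seg_cost_col(h, m, j)[cand + 1L]  # cost(t+1, j)
            val <- D[k - 1L, cand] + costs
            target <- D[k, j]
            t <- cand[which(val <= target + tol)[1]]
            bounds <- c(t, bounds)
            j <- t
        }
    }
    starts <- c(1L, bounds + 1L)
    ends <- c(bounds, n)
    segTable(h, m, starts, ends)
}

segTable <- function(h, m, starts, ends) {
    ch <- cumsum(h); cm <- cumsum(m)
    H <- ch[ends] - c(0, ch)[starts]
    M <- cm[ends] - c(0, cm)[starts]
    data.frame(start = starts, end = ends, nSnps = ends - starts + 1L,
               het = H, nonmissing = M, rate = ifelse(M > 0, H / M, NA_real_))
}

#' @export
print.BernoulliSegmentation <- function(x, ...) {
    cat("Bernoulli segmentation of", x$chrom, "-", x$n, "SNPs, K = 1..",
        x$Kmax, "\n")
    cat("logLik range:", sprintf("%.3f .. %.3f", x$logLik[1],
                                 x$logLik[x$Kmax]), "\n")
    invisible(x)
}

#' Select the number of segments
#'
#' Penalized model selection on the per-K optimal log-likelihoods with
#' penalty shape pen(K) = K (1 + log(n/K)).  The penalty constant is
#' calibrated by the slope heuristic: the slope of logLik against pen(K)
#' over the upper half of the fitted K range estimates the pure-noise
#' gain, and twice that slope is used as the penalty multiplier.  A BIC
#' criterion is available as an alternative.  Degenerate cases (short K
#' ranges, non-positive slopes) fall back to the smallest K whose
#' log-likelihood is within tolerance of the maximum.
#'
#' @param seg a \code{"BernoulliSegmentation"} (or a numeric vector of
#'   log-likelihoods for K = 1, 2, ...).
#' @param n number of SNPs (taken from \code{seg} when available).
#' @param crit \code{"slope"} (default) or \code{"bic"}.
#' @param tol tolerance of the degenerate fallback.
#' @return the selected K (integer).
#' @export
selectK <- function(seg, n = NULL, crit = c("slope", "bic"), tol = 1e-8) {
    crit <- match.arg(crit)
    if (inherits(seg, "BernoulliSegmentation")) {
        ll <- seg$logLik
        if (is.null(n)) n <- seg$n
        M <- sum(seg$m)
    } else {
        ll <- as.numeric(seg)
        if (is.null(n)) stop("n is required when passing raw log-likelihoods")
        M <- n
    }
    Kmax <- length(ll)
    if (Kmax == 1) return(1L)
    K <- seq_len(Kmax)
    pen <- K * (1 + log(n / K))
    if (crit == "bic") {
        sc <- ll - 0.5 * (2 * K - 1) * log(M)
        return(which.max(sc))
    }
    if (Kmax < 4)
        return(min(which(ll >= max(ll) - tol)))
    upper <- K >= ceiling(Kmax / 2)
    fit <- stats::lm(ll[upper] ~ pen[upper])
    slope <- unname(stats::coef(fit)[2])
    if (!is.finite(slope) || slope <= 0)
        return(min(which(ll >= max(ll) - tol)))
    beta <- 2 * slope
    which.max(ll - beta * pen)
}

#' One-sided exact binomial test of a segment's heterozygosity rate
#'
#' Tests H0: segment rate equals the genome-wide rate p_g against
#' H1: rate above p_g, with the segment's non-missing cells as Bernoulli
#' trials: p = P(X >= k | n, p_g).  The upper tail is accumulated by
#' direct summation of the binomial pmf in log space.
#'
#' @param k heterozygous cells in the segment.
#' @param n non-missing cells in the segment (>= 1).
#' @param pg genome-wide heterozygosity rate, strictly inside (0, 1).
#' @return the one-sided p-value.
#' @export
exactSegmentTest <- function(k, n, pg) {
    if (length(k) > 1 || length(n) > 1)
        return(mapply(exactSegmentTest, k, n, MoreArgs = list(pg = pg)))
    if (pg <= 0 || pg >= 1) stop("pg must lie strictly inside (0, 1)")
    if (n < 1) stop("segment must have at least one non-missing cell")
    if (k <= 0) return(1)
    if (k > n) return(0)
    logsum <- function(lp) {
        mx <- max(lp)
        mx + log(sum(exp(lp - mx)))
    }
    if (k - 1 <= n * pg) {
        ## small lower tail complement: 1 - P(X <= k-1)
        lo <- stats::dbinom(0:(k - 1), n, pg, log = TRUE)
        p <- 1 - exp(logsum(lo))
        max(p, 0)
    } else {
        hi <- stats::dbinom(k:n, n, pg, log = TRUE)
        exp(logsum(hi))
    }
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up FDR adjustment (monotone q-values).
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @return q-values of the same length.
#' @export
bhAdjust <- function(p) {
    stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
    stats::p.adjust(p, method = "BH")
}

## attach exact test + BH significance to a segment table
testSegments <- function(segs, pg, fdr = 0.05) {
    segs$p <- exactSegmentTest(segs$het, segs$nonmissing, pg)
    segs$q <- bhAdjust(segs$p)
    segs$significant <- segs$q <= fdr
    segs
}

#' Merge and filter tested segments
#'
#' Post-processing of a tested segmentation: (1) merge adjacent segments
#' of equal status (significant / non-significant), pooling their
#' counts; (2) remove single-SNP segments; (3) merge again; (4) keep
#' segments with at least \code{minSnps} SNPs.  Merged segments are
#' re-tested on their pooled counts and re-adjusted by
#' Benjamini-Hochberg.
#'
#' @param segs data.frame from \code{testSegments} (columns start, end,
#'   nSnps, het, nonmissing, significant).
#' @param pg genome-wide heterozygosity rate used in re-testing.
#' @param minSnps minimum SNPs for a final segment (default 5).
#' @param fdr nominal FDR level (default 0.05).
#' @return the final segment data.frame.
#' @export
mergeAndFilter <- function(segs, pg, minSnps = 5L, fdr = 0.05) {
    mergeRuns <- function(d) {
        if (nrow(d) < 2) return(d)
        r <- rle(d$significant)
        grp <- rep(seq_along(r$lengths), r$lengths)
        out <- do.call(rbind, lapply(split(d, grp), function(b)
            data.frame(start = min(b$start), end = max(b$end),
                       nSnps = sum(b$nSnps), het = sum(b$het),
                       nonmissing = sum(b$nonmissing),
                       significant = b$significant[1])))
        rownames(out) <- NULL
        out
    }
    d <- segs[, c("start", "end", "nSnps", "het", "nonmissing",
                  "significant")]
    d <- mergeRuns(d)
    d <- d[d$nSnps > 1L, , drop = FALSE]
    d <- mergeRuns(d)
    d <- d[d$nSnps >= minSnps, , drop = FALSE]
    ## removals can leave same-status neighbors adjacent again
    d <- mergeRuns(d)
    if (nrow(d) == 0) {
        d$rate <- d$p <- d$q <- numeric(0)
        return(d)
    }
    d$rate <- ifelse(d$nonmissing > 0, d$het / d$nonmissing, NA_real_)
    d$p <- exactSegmentTest(d$het, d$nonmissing, pg)
    d$q <- bhAdjust(d$p)
    d$significant <- d$q <= fdr
    rownames(d) <- NULL
    d
}

#' Segment a heterozygosity profile end to end
#'
#' Convenience wrapper: segmentation for K = 1..Kmax, model selection,
#' exact testing against the genome-wide rate, FDR control, and the
#' merge/filter rules.  The genome-wide rate defaults to the pooled
#' heterozygous fraction of the profile itself.
#'
#' @param profile a \linkS4class{HetProfile}.
#' @param Kmax passed to \code{\link{segmentChromosome}}.
#' @param pg genome-wide heterozygosity rate; pooled observed rate when
#'   NULL.
#' @param fdr nominal FDR level (default 0.05).
#' @param minSnps minimum SNPs per final segment (default 5).
#' @param crit model selection criterion, see \code{\link{selectK}}.
#' @return list with \code{segments} (final table with bp intervals),
#'   \code{K}, \code{pg} and the underlying \code{segmentation}.
#' @export
hetSegments <- function(profile, Kmax = NULL, pg = NULL, fdr = 0.05,
                        minSnps = 5L, crit = "slope") {
    seg <- segmentChromosome(profile, Kmax = Kmax)
    K <- selectK(seg, crit = crit)
    segs <- testSegments(seg$segments[[K]], pg = if (is.null(pg))
        sum(seg$h) / sum(seg$m) else pg, fdr = fdr)
    pgUse <- if (is.null(pg)) sum(seg$h) / sum(seg$m) else pg
    final <- mergeAndFilter(segs, pg = pgUse, minSnps = minSnps, fdr = fdr)
    if (nrow(final)) {
        final$startBp <- seg$positions[final$start]
        final$endBp <- seg$positions[final$end]
        final$chrom <- seg$chrom
    }
    list(segments = final, K = K, pg = pgUse, segmentation = seg)
}

#' Re-test heterozygous segments in a doubled-haploid panel
#'
#' Doubled haploids are fully homozygous, so any heterozygosity they show
#' inside a segment is an alignment artifact (e.g. a collapsed structural
#' variant).  Each segment with at least \code{minSnps} SNPs in the DH
#' profile is re-tested against the DH genome-wide rate; segments
#' significant after BH control are class 2 (structural-variant
#' artifact), the rest class 1 (inbreeding-depression candidates).
#' Segments with too few DH SNPs are flagged untestable (class NA).
#'
#' @param segments final segment table from \code{\link{hetSegments}}
#'   (needs startBp/endBp).
#' @param dhProfile a \linkS4class{HetProfile} of the DH lines.
#' @param minSnps minimum DH SNPs for testability (default 5).
#' @param fdr nominal FDR level (default 0.05).
#' @return the segment table with dhSnps, dhP, dhQ and class columns.
#' @export
validateInDh <- function(segments, dhProfile, minSnps = 5L, fdr = 0.05) {
    X <- dhProfile@X; pos <- dhProfile@positions
    tot <- sum(!is.na(X)); het <- sum(X == 1L, na.rm = TRUE)
    pgDh <- max(het / tot, .Machine$double.eps)
    if (pgDh >= 1) stop("degenerate DH profile (all heterozygous)")
    res <- segments
    res$dhSnps <- 0L; res$dhP <- NA_real_
    for (i in seq_len(nrow(res))) {
        j <- which(pos >= res$startBp[i] & pos <= res$endBp[i])
        res$dhSnps[i] <- length(j)
        if (length(j) >= minSnps) {
            sub <- X[, j, drop = FALSE]
            M <- sum(!is.na(sub)); H <- sum(sub == 1L, na.rm = TRUE)
            if (M > 0) res$dhP[i] <- exactSegmentTest(H, M, pgDh)
        }
    }
    testable <- !is.na(res$dhP)
    res$dhQ <- NA_real_
    res$dhQ[testable] <- bhAdjust(res$dhP[testable])
    res$class <- NA_integer_
    res$class[testable] <- ifelse(res$dhQ[testable] <= fdr, 2L, 1L)
    res
}

#' Number of contributing lines per heterozygous segment
#'
#' Counts, for each segment, the lines carrying at least one heterozygous
#' call inside it, and tabulates the distribution.
#'
#' @param segments final segment table (startBp/endBp).
#' @param profile the \linkS4class{HetProfile} the segments came from.
#' @return list(contributors = per-segment counts, histogram = table).
#' @export
contributorDistribution <- function(segments, profile) {
    X <- profile@X; pos <- profile@positions
    contrib <- vapply(seq_len(nrow(segments)), function(i) {
        j <- which(pos >= segments$startBp[i] & pos <= segments$endBp[i])
        sum(rowSums(X[, j, drop = FALSE] == 1L, na.rm = TRUE) > 0)
    }, integer(1))
    list(contributors = contrib, histogram = table(contrib))
}

#' Enrichment of deleterious variants inside heterozygous segments
#'
#' 2x2 chi-square test (1 df, no continuity correction by default) of
#' deleterious vs tolerated variant proportions inside vs outside
#' segments, for genic variants.
#'
#' @param inSegment logical per variant: inside a heterozygous segment.
#' @param deleterious logical per variant: predicted deleterious (vs
#'   tolerated).
#' @param correct apply the continuity correction (default FALSE).
#' @return list(statistic, df, p.value, table); all NA with a note when a
#'   margin is empty.
#' @export
deleteriousEnrichment <- function(inSegment, deleterious, correct = FALSE) {
    tab <- table(factor(inSegment, c(FALSE, TRUE)),
                 factor(deleterious, c(FALSE, TRUE)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        return(list(statistic = NA_real_, df = NA_integer_,
                    p.value = NA_real_, table = tab,
                    note = "inapplicable: zero margin"))
    ct <- stats::chisq.test(tab, correct = correct)
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p.value = ct$p.value, table = tab)
}
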