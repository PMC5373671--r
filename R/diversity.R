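## Diversity statistics operate on the haploid 0/1 dosage view
## (heterozygotes treated as missing; inbred lines).

## per-site derived/alternate counts k and sample sizes n from a dosage
## matrix (sites x lines)
siteCounts <- function(dos) {
    n <- rowSums(!is.na(dos))
    k <- rowSums(dos == 1L, na.rm = TRUE)
    list(k = k, n = n)
}

asDosage <- function(x) {
    if (is(x, "GenotypeCalls")) haploidDosage(x) else as.matrix(x)
}

#' Site frequency spectrum with hypergeometric projection
#'
#' Projects every site down to a common sample size m: the expected
#' number of derived (or alternate) alleles in a hypergeometric
#' subsample of size m is added to the spectrum, giving a deterministic,
#' possibly fractional spectrum.  Sites with fewer than m non-missing
#' genotypes are skipped, as is projected mass on the monomorphic
#' classes 0 and m.  Without outgroup information the spectrum is folded
#' (minor-allele classes 1..floor(m/2)).
#'
#' @param x a \linkS4class{GenotypeCalls} or 0/1 dosage matrix
#'   (sites x lines).
#' @param m projection sample size (>= 2).
#' @param ancestral optional per-site ancestral allele (1 or 2, NA =
#'   unknown -- site skipped); when provided the spectrum is unfolded
#'   with "1" meaning allele 2 is derived etc.
#' @return list with \code{sfs} (named class counts), \code{m},
#'   \code{folded}, \code{nSitesUsed}.
#' @export
buildSfs <- function(x, m, ancestral = NULL) {
    if (m < 2) stop("projection size m must be >= 2")
    dos <- asDosage(x)
    sc <- siteCounts(dos)
    k <- sc$k; n <- sc$n
    folded <- is.null(ancestral)
    if (!folded) {
        stopifnot(length(ancestral) == nrow(dos))
        keep <- !is.na(ancestral)
        ## derived count: allele 2 when ancestral is allele 1, else flipped
        k <- ifelse(ancestral == 1L, k, n - k)
        k <- k[keep]; n <- n[keep]
    }
    use <- n >= m & k > 0 & k < n
    k <- k[use]; n <- n[use]
    u <- numeric(m + 1)  # classes 0..m of the projected derived count
    for (j in 0:m)
        u[j + 1] <- sum(stats::dhyper(j, k, n - k, m))
    if (folded) {
        half <- floor(m / 2)
        f <- numeric(half)
        for (j in seq_len(half))
            f[j] <- if (j == m - j) u[j + 1] else u[j + 1] + u[m - j + 1]
        sfs <- stats::setNames(f, seq_len(half))
    } else {
        sfs <- stats::setNames(u[2:m], seq_len(m - 1))
    }
    list(sfs = sfs, m = m, folded = folded, nSitesUsed = length(k))
}

#' Fold an unfolded spectrum
#'
#' @param sfs named unfolded class counts (classes 1..m-1).
#' @param m the projection size.
#' @return folded class counts (classes 1..floor(m/2)).
#' @export
foldSfs <- function(sfs, m) {
    u <- numeric(m + 1)
    u[as.integer(names(sfs)) + 1] <- sfs
    half <- floor(m / 2)
    f <- vapply(seq_len(half), function(j)
        if (j == m - j) u[j + 1] else u[j + 1] + u[m - j + 1], numeric(1))
    stats::setNames(f, seq_len(half))
}

## harmonic numbers a1 = sum 1/i and a2 = sum 1/i^2, i = 1..n-1
harmonic1 <- function(n) vapply(n, function(x)
    if (x < 2) NA_real_ else sum(1 / seq_len(x - 1)), numeric(1))
harmonic2 <- function(n) vapply(n, function(x)
    if (x < 2) NA_real_ else sum(1 / seq_len(x - 1)^2), numeric(1))

#' Nucleotide diversity, Watterson's theta and Tajima's D with missing
#' data
#'
#' Per-site corrections for missing genotypes: a site with k alternate
#' alleles among n_i non-missing contributes 2 k (n_i - k) /
#' (n_i (n_i - 1)) to pi, and each segregating site contributes
#' 1/a1(n_i) to Watterson's theta, with a1 the harmonic number of its
#' own sample size.  Tajima's D normalizes pi - theta with the standard
#' variance formula evaluated at the average per-site sample size
#' (rounded) and the observed number of segregating sites.
#'
#' @param x a \linkS4class{GenotypeCalls} or 0/1 dosage matrix.
#' @param perBp optional number of covered bases; when given, pi and
#'   theta are also returned per bp.
#' @return list(pi, theta, D, S, nbar; piPerBp/thetaPerBp when perBp is
#'   given).
#' @export
piThetaD <- function(x, perBp = NULL) {
    dos <- asDosage(x)
    sc <- siteCounts(dos)
    use <- sc$n >= 2
    k <- sc$k[use]; n <- sc$n[use]
    seg <- k > 0 & k < n
    pi <- sum(2 * k * (n - k) / (n * (n - 1)))
    theta <- sum(1 / harmonic1(n[seg]))
    S <- sum(seg)
    if (S == 0)
        return(list(pi = pi, theta = theta, D = NA_real_, S = 0L,
                    nbar = if (length(n)) round(mean(n)) else NA))
    nbar <- max(round(mean(n[seg])), 2)
    D <- if (nbar < 4 || S < 1) NA_real_ else {
        a1 <- harmonic1(nbar); a2 <- harmonic2(nbar)
        b1 <- (nbar + 1) / (3 * (nbar - 1))
        b2 <- 2 * (nbar^2 + nbar + 3) / (9 * nbar * (nbar - 1))
        c1 <- b1 - 1 / a1
        c2 <- b2 - (nbar + 2) / (a1 * nbar) + a2 / a1^2
        e1 <- c1 / a1
        e2 <- c2 / (a1^2 + a2)
        v <- e1 * S + e2 * S * (S - 1)
        if (v <= 0) NA_real_ else (pi - theta) / sqrt(v)
    }
    out <- list(pi = pi, theta = theta, D = D, S = S, nbar = nbar)
    if (!is.null(perBp)) {
        out$piPerBp <- pi / perBp
        out$thetaPerBp <- theta / perBp
    }
    out
}

#' Sliding-window diversity scan
#'
#' Computes pi, Watterson's theta, Tajima's D and mean Nei's H on
#' sliding bp windows (0-based half-open coordinates).  Windows whose
#' sites average more than 50% missing genotypes, or that contain no
#' sites, are excluded.  Using \code{step = window} gives the
#' non-overlapping mode.
#'
#' @param x a \linkS4class{GenotypeCalls} (positions from rowRanges) or a
#'   dosage matrix with \code{positions}.
#' @param window window size in bp (default 50000).
#' @param step step in bp (default 10000).
#' @param positions site bp positions when \code{x} is a matrix.
#' @param chromLength chromosome length (default: max position).
#' @param maxMissing exclusion threshold on the window mean missing
#'   fraction (default 0.5).
#' @return data.frame of window statistics (one row per retained
#'   window).
#' @export
windowScan <- function(x, window = 50000L, step = 10000L, positions = NULL,
                       chromLength = NULL, maxMissing = 0.5) {
    dos <- asDosage(x)
    if (is.null(positions))
        positions <- if (is(x, "GenotypeCalls"))
            start(rowRanges(x)) else seq_len(nrow(dos))
    if (is.unsorted(positions)) stop("positions must be sorted")
    if (is.null(chromLength)) chromLength <- max(positions)
    starts <- seq(0, chromLength - window, by = step)
    rows <- lapply(starts, function(s) {
        idx <- which(positions > s & positions <= s + window)
        if (!length(idx)) return(NULL)
        sub <- dos[idx, , drop = FALSE]
        missFrac <- mean(is.na(sub))
        if (missFrac > maxMissing) return(NULL)
        st <- piThetaD(sub)
        data.frame(start = s, end = s + window, nSites = length(idx),
                   piPerBp = st$pi / window, thetaPerBp = st$theta / window,
                   D = st$D, neiH = meanNeiH(sub), missingFrac = missFrac)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(start = numeric(0), end = numeric(0),
                          nSites = integer(0), piPerBp = numeric(0),
                          thetaPerBp = numeric(0), D = numeric(0),
                          neiH = numeric(0), missingFrac = numeric(0))
    out
}

## unbiased per-site Nei's gene diversity 2p(1-p) n/(n-1), averaged
meanNeiH <- function(dos) {
    sc <- siteCounts(dos)
    use <- sc$n >= 2
    if (!any(use)) return(NA_real_)
    p <- sc$k[use] / sc$n[use]
    n <- sc$n[use]
    mean(2 * p * (1 - p) * n / (n - 1))
}

#' Nei's H along SNP-indexed sliding windows
#'
#' Per-site unbiased gene diversity H = 2 p (1-p) n/(n-1) within a
#' group, averaged over sliding windows of \code{window} SNPs with a
#' step of \code{step} SNPs.
#'
#' @param x a \linkS4class{GenotypeCalls} or dosage matrix.
#' @param group group label (matched against \code{lineGroups}) or
#'   column indices; NULL = all lines.
#' @param window window length in SNPs (default 1000).
#' @param step step in SNPs (default 1).
#' @return data.frame with the window center SNP index and mean H.
#' @export
neiHScan <- function(x, group = NULL, window = 1000L, step = 1L) {
    dos <- asDosage(x)
    if (!is.null(group)) {
        cols <- if (is.character(group)) which(lineGroups(x) == group)
                else group
        if (length(cols) < 2) stop("groups of size < 2 are rejected")
        dos <- dos[, cols, drop = FALSE]
    } else if (ncol(dos) < 2) stop("groups of size < 2 are rejected")
    sc <- siteCounts(dos)
    h <- ifelse(sc$n >= 2,
                2 * (sc$k / sc$n) * (1 - sc$k / sc$n) * sc$n / (sc$n - 1), NA)
    ns <- length(h)
    if (ns < window) stop("fewer SNPs than the window length")
    starts <- seq(1L, ns - window + 1L, by = step)
    ch <- cumsum(ifelse(is.na(h), 0, h))
    cn <- cumsum(!is.na(h))
    H <- (ch[starts + window - 1L] - c(0, ch)[starts]) /
        (cn[starts + window - 1L] - c(0, cn)[starts])
    data.frame(startSnp = starts, endSnp = starts + window - 1L,
               centerSnp = starts + (window - 1L) / 2, H = H)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared correlation of 0/1 allele indicators on pairwise-complete
#' lines (heterozygotes already treated as missing).  Monomorphic sites
#' yield NA.
#'
#' @param x a \linkS4class{GenotypeCalls} or dosage matrix.
#' @param sites indices of the sites to correlate (default: all).
#' @return symmetric matrix of r-squared values.
#' @export
ldR2 <- function(x, sites = NULL) {
    dos <- asDosage(x)
    if (!is.null(sites)) dos <- dos[sites, , drop = FALSE]
    r <- suppressWarnings(stats::cor(t(dos), use = "pairwise.complete.obs"))
    r * r
}

#' Paired comparison of per-window diversity
#'
#' Two-sided Wilcoxon signed-rank test on paired per-window nucleotide
#' diversity of two samples over the same windows.  Identical vectors
#' (all zero differences) return p = 1 by convention.
#'
#' @param a,b paired numeric vectors (same windows, both non-missing).
#' @return list(p.value, statistic, nPairs).
#' @export
compareDiversity <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    stopifnot(length(a) == length(b))
    if (length(a) < 10)
        warning("fewer than 10 paired windows; the test has little power")
    if (all(a == b))
        return(list(p.value = 1, statistic = NA_real_, nPairs = length(a)))
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
    list(p.value = wt$p.value, statistic = unname(wt$statistic),
         nPairs = length(a))
}
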