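#' Partition a genome into genic regions and non-genic controls
#'
#' Genic regions are gene bodies extended by \code{flank} bp on both
#' sides (overlapping genes merged first).  Non-genic control windows are
#' drawn from the compartment farther than \code{controlDistance} bp from
#' every gene, with lengths sampled from the genic-region lengths so the
#' controls match them in size.
#'
#' @param genes \linkS4class{GRanges} of gene bodies (\code{gene_id}
#'   metadata column optional).
#' @param genomeLength chromosome length in bp.
#' @param flank genic flank (default 10000 bp).
#' @param controlDistance minimum distance of controls from genes
#'   (default 50000 bp).
#' @param nControls number of control windows to draw (default 1000).
#' @param seed integer seed for control placement.
#' @return \linkS4class{GRanges} with metadata columns \code{kind}
#'   ("genic"/"nongenic") and \code{region_id}.
#' @export
partitionRegions <- function(genes, genomeLength, flank = 10000L,
                             controlDistance = 50000L, nControls = 1000L,
                             seed = 1L) {
    set.seed(seed)
    chrom <- if (length(genes)) as.character(seqnames(genes)[1]) else "chr1"
    genic <- GenomicRanges::reduce(genes + flank)
    genic <- GenomicRanges::restrict(genic, start = 1, end = genomeLength)
    if (length(genes) && !is.null(genes$gene_id)) {
        ## keep one id per merged genic region (first overlapping gene)
        ov <- GenomicRanges::findOverlaps(genic, genes)
        first <- !duplicated(S4Vectors::queryHits(ov))
        genic$region_id <- genes$gene_id[S4Vectors::subjectHits(ov)[first]]
    } else {
        genic$region_id <- sprintf("genic%04d", seq_along(genic))
    }
    chromGr <- GRanges(chrom, IRanges(1, genomeLength))
    mask <- if (length(genes))
        GenomicRanges::setdiff(chromGr, GenomicRanges::reduce(
            genes + controlDistance))
    else chromGr
    widths <- if (length(genic)) width(genic) else 20000L
    lens <- widths[sample.int(length(widths), nControls, replace = TRUE)]
    fits <- lapply(seq_len(nControls), function(i) {
        ok <- which(width(mask) >= lens[i])
        if (!length(ok)) return(NULL)
        j <- ok[sample.int(length(ok), 1)]
        s <- start(mask)[j] +
            floor(stats::runif(1) * (width(mask)[j] - lens[i] + 1))
        GRanges(chrom, IRanges(s, width = lens[i]))
    })
    fits <- fits[!vapply(fits, is.null, logical(1))]
    if (!length(fits))
        stop("genome too small: no non-genic control window fits")
    controls <- do.call(c, fits)
    controls$region_id <- sprintf("control%04d", seq_along(controls))
    genic$kind <- "genic"
    controls$kind <- "nongenic"
    out <- c(genic, controls)
    out
}

#' Weir-Cockerham Fst between two groups over a set of sites
#'
#' Multi-locus ratio-of-sums variance-components estimator for haploid
#' samples (appropriate for small sample sizes): per site, with group
#' allele counts n_i and frequencies p_i, the among-group and
#' within-group components are accumulated across sites and their ratio
#' is returned.
#'
#' @param x a \linkS4class{GenotypeCalls} or 0/1 dosage matrix.
#' @param groupA,groupB group labels (against \code{lineGroups}) or
#'   column index vectors.
#' @param sites optional site indices restricting the estimate.
#' @return the multi-locus Fst estimate (NA when no usable site).
#' @export
wcFst <- function(x, groupA, groupB, sites = NULL) {
    dos <- asDosage(x)
    colsOf <- function(g) if (is.character(g) && length(g) == 1)
        which(lineGroups(x) == g) else g
    ca <- colsOf(groupA); cb <- colsOf(groupB)
    if (!is.null(sites)) dos <- dos[sites, , drop = FALSE]
    da <- dos[, ca, drop = FALSE]; db <- dos[, cb, drop = FALSE]
    comp <- wcFstComponents(da, db)
    if (comp$den == 0) return(NA_real_)
    comp$num / comp$den
}

## per-site W&C components summed over sites; haploid samples, 2 groups
wcFstComponents <- function(da, db) {
    n1 <- rowSums(!is.na(da)); n2 <- rowSums(!is.na(db))
    k1 <- rowSums(da == 1L, na.rm = TRUE); k2 <- rowSums(db == 1L, na.rm = TRUE)
    use <- n1 >= 2 & n2 >= 2
    n1 <- n1[use]; n2 <- n2[use]; k1 <- k1[use]; k2 <- k2[use]
    p1 <- k1 / n1; p2 <- k2 / n2
    nt <- n1 + n2
    pbar <- (k1 + k2) / nt
    r <- 2
    msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
    msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nt - r)
    nc <- (nt - (n1^2 + n2^2) / nt) / (r - 1)
    a <- (msp - msg) / nc
    list(num = sum(a), den = sum(a + msg), perSiteA = a, perSiteB = msg)
}

#' Empirical p-value against non-genic control values
#'
#' p = (1 + \#controls at least as extreme) / (1 + \#controls); the
#' pseudo-count keeps p strictly above zero.  \code{tail = "upper"}
#' counts controls >= the value (differentiation statistics);
#' \code{"lower"} counts controls <= the value (Tajima's D).
#'
#' @param stat observed statistic (vectorized).
#' @param controls numeric vector of control-region values.
#' @param tail "upper" or "lower".
#' @param minControls minimum usable controls (default 100).
#' @return empirical p-value(s) in (0, 1\].
#' @export
empiricalPvalue <- function(stat, controls, tail = c("upper", "lower"),
                            minControls = 100L) {
    tail <- match.arg(tail)
    controls <- controls[!is.na(controls)]
    if (length(controls) < minControls)
        stop("need at least ", minControls, " control values")
    vapply(stat, function(s) {
        if (is.na(s)) return(NA_real_)
        extreme <- if (tail == "upper") sum(controls >= s)
                   else sum(controls <= s)
        (1 + extreme) / (1 + length(controls))
    }, numeric(1))
}

#' Import externally computed XP-CLR window scores
#'
#' Reads a TSV of per-window XP-CLR scores (chrom, start, end, score,
#' direction) computed outside the pipeline and assigns each region the
#' maximum overlapping window score per direction.
#'
#' @param scores a file path or data.frame with columns chrom, start,
#'   end, score, direction.
#' @param regions \linkS4class{GRanges} of regions (from
#'   \code{\link{partitionRegions}}).
#' @return data.frame region_id x direction with the max score (NA when
#'   no window overlaps).
#' @export
importXpclr <- function(scores, regions) {
    if (is.character(scores)) {
        scores <- data.table::fread(scores, sep = "\t", data.table = FALSE)
    }
    need <- c("chrom", "start", "end", "score", "direction")
    if (!all(need %in% names(scores)))
        stop("score table must have columns: ", paste(need, collapse = ", "))
    bad <- which(!is.finite(scores$score) | scores$end < scores$start)
    if (length(bad))
        stop("malformed score rows at lines: ", paste(bad, collapse = ", "))
    gr <- GRanges(scores$chrom, IRanges(scores$start, scores$end))
    dirs <- unique(scores$direction)
    out <- data.frame(region_id = regions$region_id)
    for (d in dirs) {
        sel <- scores$direction == d
        ov <- GenomicRanges::findOverlaps(regions, gr[sel])
        val <- rep(NA_real_, length(regions))
        if (length(ov)) {
            agg <- tapply(scores$score[sel][S4Vectors::subjectHits(ov)],
                          S4Vectors::queryHits(ov), max)
            val[as.integer(names(agg))] <- agg
        }
        out[[paste0("xpclr_", d)]] <- val
    }
    out
}

#' Call differentially selected candidate genes
#'
#' A genic region is a candidate when all three conditions hold: (1) the
#' Fst empirical p-value is below alpha; (2) the XP-CLR empirical p is
#' below alpha in at least one of the two reciprocal directions; (3)
#' Tajima's D is negative with empirical p below alpha in at least one
#' of the two groups.  The table records which group(s) carry the D
#' signal.
#'
#' @param stats data.frame with columns region_id, fstP, xpclrP1,
#'   xpclrP2, d1, d2, dP1, dP2 (groups 1/2; directions 1/2).
#' @param alpha significance threshold (default 0.05).
#' @return the table with candidate flag and dGroup columns; rows with
#'   missing statistics are excluded and counted in
#'   \code{attr(, "nExcluded")}.
#' @export
callDsCandidates <- function(stats, alpha = 0.05) {
    need <- c("fstP", "xpclrP1", "xpclrP2", "d1", "d2", "dP1", "dP2")
    miss <- !stats::complete.cases(stats[, need])
    out <- stats[!miss, , drop = FALSE]
    sigD1 <- out$d1 < 0 & out$dP1 < alpha
    sigD2 <- out$d2 < 0 & out$dP2 < alpha
    out$candidate <- out$fstP < alpha &
        (out$xpclrP1 < alpha | out$xpclrP2 < alpha) & (sigD1 | sigD2)
    out$dGroup <- ifelse(sigD1 & sigD2, "both",
                         ifelse(sigD1, "group1",
                                ifelse(sigD2, "group2", "none")))
    attr(out, "nExcluded") <- sum(miss)
    out
}

#' Expected number of false-positive candidates
#'
#' The fraction of non-genic control regions that pass all three 5%
#' thresholds, multiplied by the number of genes tested, estimates the
#' expected false-positive count of the combined rule under the null.
#'
#' @param controlStats control-region table in the format of
#'   \code{\link{callDsCandidates}}.
#' @param nGenes number of genes tested.
#' @param alpha threshold (default 0.05).
#' @return list(fraction, expected).
#' @export
expectedFalsePositives <- function(controlStats, nGenes, alpha = 0.05) {
    cc <- callDsCandidates(controlStats, alpha = alpha)
    frac <- if (nrow(cc)) mean(cc$candidate) else 0
    list(fraction = frac, expected = frac * nGenes)
}

#' Per-region selection statistics for one group comparison
#'
#' For every region computes the SNP count and per-group missing
#' fractions, applies the analyzability rule (more than \code{minSnps}
#' SNPs and at most \code{maxMissing} missing per group), and returns
#' Weir-Cockerham Fst between the two groups and Tajima's D within each.
#'
#' @param gm a \linkS4class{GenotypeCalls} with group labels.
#' @param regions \linkS4class{GRanges} from
#'   \code{\link{partitionRegions}}.
#' @param groupA,groupB the two group labels.
#' @param minSnps analyzable regions need more SNPs than this
#'   (default 7).
#' @param maxMissing maximum per-group missing fraction (default 0.3).
#' @return data.frame of per-region statistics (non-analyzable regions
#'   have NA).
#' @export
regionStats <- function(gm, regions, groupA, groupB, minSnps = 7L,
                        maxMissing = 0.3) {
    dos <- haploidDosage(gm)
    grp <- lineGroups(gm)
    ca <- which(grp == groupA); cb <- which(grp == groupB)
    pos <- start(rowRanges(gm))
    res <- data.frame(region_id = regions$region_id, kind = regions$kind,
                      nSnps = 0L, missA = NA_real_, missB = NA_real_,
                      fst = NA_real_, dA = NA_real_, dB = NA_real_)
    for (i in seq_along(regions)) {
        idx <- which(pos >= start(regions)[i] & pos <= end(regions)[i])
        res$nSnps[i] <- length(idx)
        if (length(idx) <= minSnps) next
        subA <- dos[idx, ca, drop = FALSE]
        subB <- dos[idx, cb, drop = FALSE]
        res$missA[i] <- mean(is.na(subA))
        res$missB[i] <- mean(is.na(subB))
        if (res$missA[i] > maxMissing || res$missB[i] > maxMissing) next
        comp <- wcFstComponents(subA, subB)
        res$fst[i] <- if (comp$den == 0) NA_real_ else comp$num / comp$den
        res$dA[i] <- piThetaD(subA)$D
        res$dB[i] <- piThetaD(subB)$D
    }
    res
}
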