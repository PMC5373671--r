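#' Genotype-caller configuration
#'
#' Parameters of the binomial likelihood-ratio caller and of the four
#' filter families applied after calling (multiple mapping, sequencing
#' depth, error rate, heterozygosity context).
#'
#' @param epsilon per-read sequencing error rate (default 0.01).
#' @param alpha test level of the likelihood-ratio call and of the
#'   error-rate filters (default 0.05).
#' @param minDepth minimum per-cell depth for a call (default 6 reads).
#' @param maxMeanDepth per-site mean depth across lines above which the
#'   site is dropped as a suspected collapsed duplication (default 28).
#' @param minUniqueFrac minimum fraction of uniquely mapping reads for a
#'   cell to be kept (default 0.90, exclusive).
#' @param indelBuffer distance (bp) to a heterozygous indel within which
#'   heterozygous calls are masked (default 500).
#' @param literalErrorRule logical; the error-count binomial rule drops a
#'   site when the upper-tail probability of its error count is small
#'   (improbably many errors).  Set TRUE to honor the literal "above
#'   alpha" reading instead (drop when the tail probability is large).
#' @return a list of class \code{"CallerConfig"}.
#' @export
callerConfig <- function(epsilon = 0.01, alpha = 0.05, minDepth = 6L,
                         maxMeanDepth = 28, minUniqueFrac = 0.90,
                         indelBuffer = 500L, literalErrorRule = FALSE) {
    if (epsilon <= 0 || epsilon >= 0.5)
        stop("epsilon must lie in (0, 0.5)")
    if (minDepth <= 0 || maxMeanDepth <= 0 || minUniqueFrac <= 0 ||
        indelBuffer < 0)
        stop("thresholds must be positive")
    structure(list(epsilon = epsilon, alpha = alpha,
                   minDepth = as.integer(minDepth),
                   maxMeanDepth = maxMeanDepth,
                   minUniqueFrac = minUniqueFrac,
                   indelBuffer = as.integer(indelBuffer),
                   literalErrorRule = literalErrorRule),
              class = "CallerConfig")
}

#' Call a genotype from the two allele read counts
#'
#' Likelihood-ratio call: with n = n1 + n2 reads, the homozygous model
#' treats the minor count n2 as sequencing errors, Binomial(n, epsilon);
#' the heterozygous model is Binomial(n, 1/2).  If twice the absolute
#' log-likelihood difference exceeds the chi-square(1) quantile at
#' 1 - alpha (3.841 at alpha = 0.05) the better-fitting genotype is
#' returned, otherwise the call is missing.  Cells with fewer than
#' \code{minDepth} reads are missing.
#'
#' @param n1,n2 integer vectors of major/minor read counts (n1 >= n2).
#' @param cfg a \code{\link{callerConfig}}.
#' @return character vector in \code{c("hom", "het", NA)}.
#' @export
callGenotype <- function(n1, n2, cfg = callerConfig()) {
    if (any(n1 < 0 | n2 < 0, na.rm = TRUE))
        stop("negative read counts")
    if (any(n1 < n2, na.rm = TRUE))
        stop("n1 must be >= n2")
    n <- n1 + n2
    llHom <- stats::dbinom(n2, n, cfg$epsilon, log = TRUE)
    llHet <- stats::dbinom(n2, n, 0.5, log = TRUE)
    lrt <- 2 * abs(llHom - llHet)
    crit <- stats::qchisq(1 - cfg$alpha, df = 1)
    out <- ifelse(lrt > crit, ifelse(llHet > llHom, "het", "hom"),
                  NA_character_)
    out[n < cfg$minDepth] <- NA_character_
    out
}

## cellwise calls on an AlleleDepths -> genotype code matrix (0/1/2/NA);
## hom calls take the identity of the cell's major allele when the
## simulator recorded it, otherwise allele 1.
callMatrix <- function(adm, cfg) {
    n1 <- assay(adm, "n1"); n2 <- assay(adm, "n2")
    call <- callGenotype(as.vector(n1), as.vector(n2), cfg)
    geno <- matrix(NA_integer_, nrow(n1), ncol(n1))
    major <- if ("majorAllele" %in% names(assays(adm)))
        as.vector(assay(adm, "majorAllele")) else 1L
    hom <- !is.na(call) & call == "hom"
    geno[hom] <- ifelse(rep(major, length.out = length(call))[hom] == 2L,
                        GENO_HOM2, GENO_HOM1)
    geno[!is.na(call) & call == "het"] <- GENO_HET
    dimnames(geno) <- dimnames(n1)
    geno
}

#' Call genotypes and apply the customized filters
#'
#' Runs the likelihood-ratio caller on every cell of an
#' \linkS4class{AlleleDepths} object, then applies the four filter
#' families in order: (1) multiple mapping -- cells with unique-mapping
#' fraction at or below \code{minUniqueFrac} are masked, and sites where
#' a masked-for-mapping cell was called heterozygous are dropped; (2)
#' sequencing depth -- cells under \code{minDepth} reads are missing and
#' sites whose mean depth across lines exceeds \code{maxMeanDepth} are
#' dropped; (3) error rate -- sites with improbably many discordant reads
#' in any cell (binomial tail below alpha), or whose error counts across
#' lines deviate from a Poisson (Kolmogorov-Smirnov at alpha), are
#' dropped; (4) heterozygosity context -- heterozygous calls near
#' heterozygous indels are masked, sites with a heterozygote but not both
#' homozygote classes are dropped, and sites monomorphic after filtering
#' are dropped.
#'
#' @param adm an \linkS4class{AlleleDepths}.
#' @param cfg a \code{\link{callerConfig}}.
#' @param indelPos optional numeric vector of heterozygous-indel bp
#'   positions (the indel rule is skipped when absent).
#' @return list with \code{calls} (a \linkS4class{GenotypeCalls} of the
#'   retained sites), \code{report} (per-site fate data.frame) and
#'   \code{fateCounts}.
#' @export
callAndFilter <- function(adm, cfg = callerConfig(), indelPos = NULL) {
    geno <- callMatrix(adm, cfg)
    ns <- nrow(geno)
    fate <- rep("retained", ns)

    dm <- filterDepthAndMapping(adm, geno, cfg)
    geno <- dm$geno
    fate[dm$dropMultimap] <- "dropped_multimap"
    fate[fate == "retained" & dm$dropDepth] <- "dropped_depth"

    ec <- filterErrorCounts(adm, geno, cfg)
    fate[fate == "retained" & ec$dropBinomial] <- "dropped_error_binomial"
    fate[fate == "retained" & ec$dropPoisson] <- "dropped_error_poisson"

    pos <- start(rowRanges(adm))
    hc <- filterHetContext(geno, pos, indelPos, cfg)
    geno <- hc$geno
    fate[fate == "retained" & hc$dropHetRule] <- "dropped_het_rule"
    fate[fate == "retained" & hc$dropMonomorphic] <- "dropped_monomorphic"

    keep <- fate == "retained"
    calls <- GenotypeCalls(geno[keep, , drop = FALSE],
                           rowRanges = rowRanges(adm)[keep],
                           lineData = colData(adm))
    report <- data.frame(site = seq_len(ns), pos = pos, fate = fate)
    list(calls = calls, report = report, fateCounts = table(fate))
}

#' Depth and multiple-mapping filters
#'
#' Cellwise, genotypes with unique-mapping fraction at or below the
#' threshold or with depth under \code{minDepth} are masked.  Sitewise,
#' sites with mean depth across lines above \code{maxMeanDepth}, and
#' sites where any cell is both multimap-ambiguous and heterozygous, are
#' flagged for dropping.
#'
#' @param adm an \linkS4class{AlleleDepths}.
#' @param geno genotype code matrix from the caller.
#' @param cfg a \code{\link{callerConfig}}.
#' @return list(geno, dropDepth, dropMultimap) -- masked matrix plus
#'   per-site logical flags.
#' @export
filterDepthAndMapping <- function(adm, geno, cfg = callerConfig()) {
    depth <- assay(adm, "n1") + assay(adm, "n2")
    uf <- assay(adm, "uniqueFrac")
    ambiguous <- uf <= cfg$minUniqueFrac
    dropMultimap <- rowSums(ambiguous & geno == GENO_HET, na.rm = TRUE) > 0
    geno[ambiguous] <- NA_integer_
    geno[depth < cfg$minDepth] <- NA_integer_
    dropDepth <- rowMeans(depth) > cfg$maxMeanDepth
    list(geno = geno, dropDepth = dropDepth, dropMultimap = dropMultimap)
}

#' Error-count filters
#'
#' The per-cell error count is the number of reads discordant with the
#' called genotype: the minor count for homozygous calls, zero for
#' heterozygous calls.  A site is flagged when (a) any cell's upper-tail
#' binomial probability P(X >= errors | depth, epsilon) falls below
#' alpha, or (b) a Kolmogorov-Smirnov test of the error counts across
#' lines against Poisson(mean error count) rejects at alpha.  Sites with
#' fewer than 2 non-missing cells skip test (b).
#'
#' @inheritParams filterDepthAndMapping
#' @return list(dropBinomial, dropPoisson) of per-site logical flags.
#' @export
filterErrorCounts <- function(adm, geno, cfg = callerConfig()) {
    n1 <- assay(adm, "n1"); n2 <- assay(adm, "n2")
    depth <- n1 + n2
    err <- matrix(NA_integer_, nrow(geno), ncol(geno))
    isHom <- !is.na(geno) & geno != GENO_HET
    err[isHom] <- n2[isHom]
    err[!is.na(geno) & geno == GENO_HET] <- 0L
    ## (a) binomial tail P(X >= err)
    tail <- matrix(NA_real_, nrow(geno), ncol(geno))
    ok <- !is.na(err)
    tail[ok] <- stats::pbinom(err[ok] - 1L, depth[ok], cfg$epsilon,
                              lower.tail = FALSE)
    flagged <- if (cfg$literalErrorRule) tail > cfg$alpha else tail < cfg$alpha
    dropBinomial <- rowSums(flagged, na.rm = TRUE) > 0
    ## (b) discrete-adapted KS against Poisson(mean): the KS distance is
    ## evaluated on the integer support and referred to the asymptotic
    ## Kolmogorov null, which is conservative for discrete data
    dropPoisson <- vapply(seq_len(nrow(err)), function(i) {
        e <- err[i, ]; e <- e[!is.na(e)]
        if (length(e) < 2) return(FALSE)
        lam <- mean(e)
        if (lam == 0) return(FALSE)
        ksDiscretePoisson(e, lam) < cfg$alpha
    }, logical(1))
    list(dropBinomial = dropBinomial, dropPoisson = dropPoisson)
}

## one-sample KS p-value of integer counts against Poisson(lambda):
## sup_x |Fn(x) - F(x)| over the integer support, asymptotic Kolmogorov
## tail Q(t) = 2 sum (-1)^(k-1) exp(-2 k^2 t^2)
ksDiscretePoisson <- function(e, lambda) {
    sup <- 0:max(e)
    Fn <- vapply(sup, function(x) mean(e <= x), numeric(1))
    D <- max(abs(Fn - stats::ppois(sup, lambda)))
    t <- sqrt(length(e)) * D
    k <- seq_len(25)
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
    min(max(p, 0), 1)
}

#' Heterozygosity-context filters
#'
#' Masks heterozygous calls within \code{indelBuffer} bp of a
#' heterozygous indel; drops sites where a heterozygote is observed but
#' both homozygote classes are not seen in other lines; drops sites
#' monomorphic after filtering.
#'
#' @param geno genotype code matrix.
#' @param pos site bp positions.
#' @param indelPos heterozygous-indel bp positions, or NULL to skip.
#' @param cfg a \code{\link{callerConfig}}.
#' @return list(geno, dropHetRule, dropMonomorphic).
#' @export
filterHetContext <- function(geno, pos, indelPos = NULL,
                             cfg = callerConfig()) {
    if (!is.null(indelPos) && length(indelPos)) {
        d <- vapply(pos, function(p) min(abs(indelPos - p)), numeric(1))
        near <- which(d < cfg$indelBuffer)
        if (length(near)) {
            sub <- geno[near, , drop = FALSE]
            sub[sub == GENO_HET] <- NA_integer_
            geno[near, ] <- sub
        }
    }
    nHet  <- rowSums(geno == GENO_HET,  na.rm = TRUE)
    nHom1 <- rowSums(geno == GENO_HOM1, na.rm = TRUE)
    nHom2 <- rowSums(geno == GENO_HOM2, na.rm = TRUE)
    dropHetRule <- nHet > 0 & (nHom1 == 0 | nHom2 == 0)
    nClasses <- (nHet > 0) + (nHom1 > 0) + (nHom2 > 0)
    dropMonomorphic <- nClasses <= 1
    list(geno = geno, dropHetRule = dropHetRule,
         dropMonomorphic = dropMonomorphic)
}

#' Per-line residual heterozygosity rate
#'
#' Rate of heterozygosity of each line relative to the reference:
#' \#het / (\#het + \#hom-alt), missing cells excluded.  Comparing each
#' line to the reference only (alternative homozygotes in the
#' denominator) makes the rate independent of the diversity of the rest
#' of the panel.  Lines with an empty denominator get NA.
#'
#' @param gm a \linkS4class{GenotypeCalls}; allele 1 is the reference.
#' @return named numeric vector, one rate per line.
#' @export
perLineHetRate <- function(gm) {
    g <- genoMatrix(gm)
    het <- colSums(g == GENO_HET, na.rm = TRUE)
    homAlt <- colSums(g == GENO_HOM2, na.rm = TRUE)
    rate <- het / (het + homAlt)
    rate[het + homAlt == 0] <- NA_real_
    rate
}

#' Concordance between two genotype matrices
#'
#' Compares calls at shared (site, line) keys: the homozygote discrepancy
#' rate over cells homozygous in both datasets; the heterozygote
#' false-positive rate (fraction of \code{a}'s heterozygotes that are
#' homozygous in \code{b}); and the false-negative rate (fraction of
#' \code{b}'s heterozygotes homozygous in \code{a}).
#'
#' @param a,b \linkS4class{GenotypeCalls} objects or genotype code
#'   matrices of identical dimension.
#' @return list(homDiscrepancy, hetFalsePositive, hetFalseNegative,
#'   nShared).
#' @export
concordanceReport <- function(a, b) {
    ga <- if (is(a, "GenotypeCalls")) genoMatrix(a) else a
    gb <- if (is(b, "GenotypeCalls")) genoMatrix(b) else b
    stopifnot(identical(dim(ga), dim(gb)))
    both <- !is.na(ga) & !is.na(gb)
    if (!any(both))
        stop("no shared non-missing (site, line) cells")
    bothHom <- both & ga != GENO_HET & gb != GENO_HET
    homDisc <- if (any(bothHom)) mean(ga[bothHom] != gb[bothHom]) else NA_real_
    aHet <- both & ga == GENO_HET
    hetFP <- if (any(aHet)) mean(gb[aHet] != GENO_HET) else NA_real_
    bHet <- both & gb == GENO_HET
    hetFN <- if (any(bHet)) mean(ga[bHet] != GENO_HET) else NA_real_
    list(homDiscrepancy = homDisc, hetFalsePositive = hetFP,
         hetFalseNegative = hetFN, nShared = sum(both))
}

#' Compare two per-gene heterozygosity-rate distributions
#'
#' Two-sided two-sample Kolmogorov-Smirnov test, used e.g. to compare
#' heterozygosity between genes with paralogs and single-copy genes.
#' Ties are handled by the standard asymptotic formula; their presence is
#' noted in the output.
#'
#' @param ratesA,ratesB non-empty numeric vectors.
#' @return list(statistic, p.value, ties).
#' @export
compareHetDistributions <- function(ratesA, ratesB) {
    stopifnot(length(ratesA) > 0, length(ratesB) > 0)
    ties <- any(duplicated(c(ratesA, ratesB)))
    kt <- suppressWarnings(stats::ks.test(ratesA, ratesB,
                                          alternative = "two.sided"))
    list(statistic = unname(kt$statistic), p.value = kt$p.value, ties = ties)
}
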