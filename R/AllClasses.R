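#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- rowRanges colData rowData
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
NULL

## Genotype codes used throughout the package: sites are rows, lines are
## columns.  0 = homozygous allele 1 (reference), 1 = heterozygous,
## 2 = homozygous allele 2 (alternate), NA = missing.
GENO_HOM1 <- 0L
GENO_HET  <- 1L
GENO_HOM2 <- 2L

#' Per-site, per-line allele read depths
#'
#' An \code{AlleleDepths} object holds, for every biallelic site and line,
#' the read counts of the two most frequent nucleotides (\code{n1 >= n2})
#' together with the per-cell fraction of uniquely mapping reads.  It
#' extends \linkS4class{RangedSummarizedExperiment}; rows are sites (with
#' genomic coordinates), columns are lines.
#'
#' @slot .  assays \code{n1}, \code{n2} (integer) and \code{uniqueFrac}
#'   (numeric in \[0,1\]).
#' @export
setClass("AlleleDepths", contains = "RangedSummarizedExperiment")

setValidity("AlleleDepths", function(object) {
    an <- names(assays(object))
    if (!all(c("n1", "n2", "uniqueFrac") %in% an))
        return("assays must contain 'n1', 'n2' and 'uniqueFrac'")
    n1 <- assay(object, "n1"); n2 <- assay(object, "n2")
    if (any(n1 < n2, na.rm = TRUE))
        return("n1 must be >= n2 in every cell")
    if (any(n2 < 0, na.rm = TRUE))
        return("negative read counts")
    uf <- assay(object, "uniqueFrac")
    if (any(uf < 0 | uf > 1, na.rm = TRUE))
        return("uniqueFrac must lie in [0, 1]")
    TRUE
})

#' Construct an AlleleDepths object
#'
#' @param n1,n2 integer matrices (sites x lines) of read counts of the most
#'   and second most frequent nucleotide; \code{n1 >= n2} cellwise.
#' @param uniqueFrac numeric matrix of the per-cell fraction of reads
#'   mapping to a unique genomic position; defaults to 1 everywhere.
#' @param rowRanges \linkS4class{GRanges} of site coordinates (one per row).
#' @param lineData \code{DataFrame} of per-line annotation (e.g. group).
#' @return an \linkS4class{AlleleDepths} object.
#' @export
AlleleDepths <- function(n1, n2, uniqueFrac = NULL, rowRanges = NULL,
                         lineData = NULL) {
    n1 <- as.matrix(n1); n2 <- as.matrix(n2)
    stopifnot(identical(dim(n1), dim(n2)))
    if (is.null(colnames(n1)))
        colnames(n1) <- colnames(n2) <- sprintf("L%02d", seq_len(ncol(n1)))
    if (is.null(uniqueFrac))
        uniqueFrac <- matrix(1, nrow(n1), ncol(n1))
    if (is.null(rowRanges))
        rowRanges <- GRanges("chr1", IRanges(seq_len(nrow(n1)), width = 1))
    if (is.null(lineData))
        lineData <- DataFrame(row.names = colnames(n1))
    se <- SummarizedExperiment(
        assays = list(n1 = n1, n2 = n2, uniqueFrac = uniqueFrac),
        rowRanges = rowRanges, colData = lineData)
    new("AlleleDepths", se)
}

#' Called genotypes for a panel of lines
#'
#' A \code{GenotypeCalls} object stores per-site, per-line genotype calls
#' for biallelic SNPs: 0 = homozygous allele 1 (reference), 1 =
#' heterozygous, 2 = homozygous allele 2, NA = missing.  Rows are sites
#' (\linkS4class{GRanges}), columns are lines; the per-line population
#' group, if any, lives in \code{colData(x)$group}.
#'
#' @export
setClass("GenotypeCalls", contains = "RangedSummarizedExperiment")

setValidity("GenotypeCalls", function(object) {
    if (!"geno" %in% names(assays(object)))
        return("assay 'geno' is required")
    g <- assay(object, "geno")
    ok <- g %in% c(GENO_HOM1, GENO_HET, GENO_HOM2) | is.na(g)
    if (!all(ok))
        return("genotype codes must be 0, 1, 2 or NA")
    TRUE
})

#' Construct a GenotypeCalls object
#'
#' @param geno integer matrix (sites x lines) with codes 0/1/2/NA.
#' @param rowRanges \linkS4class{GRanges} of site coordinates.
#' @param group optional character/factor of per-line group labels.
#' @param lineData optional \code{DataFrame} of per-line annotation.
#' @return a \linkS4class{GenotypeCalls} object.
#' @export
GenotypeCalls <- function(geno, rowRanges = NULL, group = NULL,
                          lineData = NULL) {
    geno <- as.matrix(geno)
    storage.mode(geno) <- "integer"
    if (is.null(colnames(geno)))
        colnames(geno) <- sprintf("L%02d", seq_len(ncol(geno)))
    if (is.null(rowRanges))
        rowRanges <- GRanges("chr1", IRanges(seq_len(nrow(geno)), width = 1))
    if (is.null(lineData))
        lineData <- DataFrame(row.names = colnames(geno))
    if (!is.null(group))
        lineData$group <- as.character(group)
    se <- SummarizedExperiment(assays = list(geno = geno),
                               rowRanges = rowRanges, colData = lineData)
    new("GenotypeCalls", se)
}

#' @describeIn GenotypeCalls the genotype code matrix.
#' @param x a \code{GenotypeCalls} object.
#' @export
genoMatrix <- function(x) assay(x, "geno")

#' @describeIn GenotypeCalls per-line group labels (NULL when absent).
#' @export
lineGroups <- function(x) {
    cd <- colData(x)
    if ("group" %in% names(cd)) as.character(cd$group) else NULL
}

#' Haploid dosage view of genotype calls
#'
#' Diversity and differentiation statistics in this package treat
#' heterozygous calls as missing and work on a haploid model (inbred
#' lines).  This accessor returns the 0/1 allele dosage matrix with
#' heterozygotes set to NA.
#'
#' @param x a \code{GenotypeCalls} object.
#' @return integer matrix (sites x lines): 0, 1 or NA.
#' @export
haploidDosage <- function(x) {
    g <- genoMatrix(x)
    g[g == GENO_HET] <- NA_integer_
    g[g == GENO_HOM2] <- 1L
    g
}

#' Binary heterozygosity profile of a chromosome
#'
#' Holds the line-by-SNP indicator matrix X (1 = heterozygous call,
#' 0 = homozygous, NA = missing) for one chromosome, with bp positions in
#' increasing order.  Input to \code{\link{segmentChromosome}}.
#'
#' @slot X integer matrix, lines in rows, SNPs in columns.
#' @slot positions numeric vector of bp positions, strictly increasing.
#' @slot chrom chromosome name.
#' @export
setClass("HetProfile",
    representation(X = "matrix", positions = "numeric", chrom = "character"))

setValidity("HetProfile", function(object) {
    if (ncol(object@X) != length(object@positions))
        return("ncol(X) must equal length(positions)")
    if (is.unsorted(object@positions, strictly = TRUE))
        return("positions must be strictly increasing")
    v <- object@X
    if (!all(v %in% c(0L, 1L) | is.na(v)))
        return("X entries must be 0, 1 or NA")
    TRUE
})

#' Construct a HetProfile
#'
#' @param X line-by-SNP 0/1/NA matrix of heterozygosity indicators.
#' @param positions bp positions of the SNP columns (strictly increasing).
#' @param chrom chromosome name.
#' @return a \linkS4class{HetProfile}.
#' @export
HetProfile <- function(X, positions = seq_len(ncol(X)), chrom = "chr1") {
    X <- as.matrix(X)
    storage.mode(X) <- "integer"
    new("HetProfile", X = X, positions = as.numeric(positions),
        chrom = as.character(chrom)[1])
}

#' @describeIn HetProfile number of SNP columns.
#' @param x a \code{HetProfile}.
#' @export
nSnps <- function(x) ncol(x@X)

setMethod("show", "HetProfile", function(object) {
    cat("HetProfile on", object@chrom, "-", nrow(object@X), "lines x",
        ncol(object@X), "SNPs;",
        sprintf("pooled het rate %.4g\n", mean(object@X == 1L, na.rm = TRUE)))
})

setMethod("show", "AlleleDepths", function(object) {
    cat("AlleleDepths:", nrow(object), "sites x", ncol(object), "lines\n")
    callNextMethod()
})

setMethod("show", "GenotypeCalls", function(object) {
    g <- assay(object, "geno")
    cat("GenotypeCalls:", nrow(object), "sites x", ncol(object), "lines;",
        sprintf("het %.3g%%, missing %.3g%%\n",
                100 * mean(g == GENO_HET, na.rm = TRUE),
                100 * mean(is.na(g))))
    callNextMethod()
})
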