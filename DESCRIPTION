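Package: inbredscan
Title: Genotype Calling, Residual-Heterozygosity Segmentation and
    Selection Scans for Inbred-Line Panels
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for population-genomic analysis of resequenced inbred
    line panels. Implements binomial likelihood-ratio genotype calling
    from allele read depths with filters against collapsed-paralog
    artifacts; joint Bernoulli segmentation of residual heterozygosity
    along chromosomes with exact binomial testing and false-discovery
    control; missing-data-aware diversity statistics (nucleotide
    diversity, Watterson's theta, Tajima's D) and site-frequency-spectrum
    projection; an empirical-p differential-selection scan calibrated on
    non-genic control windows; a SUMSTAT gene-network selection test; and
    the f3 three-population admixture test with block-jackknife standard
    errors. Includes seeded synthetic-data generators with known truth
    for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    data.table,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
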