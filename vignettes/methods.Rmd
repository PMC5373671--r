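---
title: "Statistical methods in inbredscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods in inbredscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inbredscan)
```

# Scope

`inbredscan` analyzes resequenced panels of inbred crop lines (maize-like:
57--67 lines at ~18x depth is the scale the defaults target). It covers
five analyses that are usually scattered over ad-hoc scripts: genotype
calling from allele depths with filters against collapsed-paralog
artifacts; segmentation of residual heterozygosity along chromosomes;
diversity statistics and site-frequency spectra under heavy missingness;
a differential-selection scan calibrated on non-genic control windows
(including a SUMSTAT gene-network test); and the f3 three-population
admixture test. Every input has a seeded synthetic generator with known
truth, so each component is testable end to end.

# Genotype calling and filters

For a biallelic site in one line, let $n_1 \ge n_2$ be the read counts of
the two nucleotides. The homozygous model treats the minor count as
sequencing errors, $n_2 \sim B(n_1+n_2, \varepsilon)$ with
$\varepsilon = 0.01$ by default; the heterozygous model is
$n_2 \sim B(n_1+n_2, 1/2)$. Twice the absolute log-likelihood difference
is referred to $\chi^2_1$: above the 95% quantile (3.841) the
better-fitting genotype is called, otherwise the cell is missing, as is
any cell under 6 reads.

Collapsed paralogs (duplicated copies missing from the reference) stack
reads from two loci onto one position and mimic heterozygosity with
inflated depth. Four filter families target them:

* *multiple mapping* — cells with a unique-mapping read fraction at or
  below 0.90 are masked; sites where such an ambiguous cell was called
  heterozygous are dropped;
* *sequencing depth* — sites whose mean depth across lines exceeds 28
  (the chosen 99% upper bound of coverage) are dropped;
* *error rate* — a site is dropped if any cell shows improbably many
  reads discordant with its call (binomial upper tail below 5%), or if
  the error counts across lines deviate from a Poisson by a
  Kolmogorov-Smirnov test. The KS distance is evaluated on the integer
  support and referred to the asymptotic Kolmogorov null; for discrete
  data this is conservative, which we prefer over the badly
  anti-conservative naive use of a continuous one-sample KS on tied
  counts. The binomial rule's direction treats "improbably many errors"
  as the rejection side; `literalErrorRule = TRUE` flips it.
* *heterozygosity context* — heterozygous calls within 500 bp of a
  heterozygous indel are masked, and a site showing a heterozygote is
  kept only if both homozygote classes occur in other lines.

On simulated counts at 18x the homozygote miscall rate is below 0.1%
and over 90% of planted collapsed-paralog sites are removed; both are
asserted by the test suite rather than quoted here.

# Segmentation of residual heterozygosity

Let $X_{ij} \in \{0,1\}$ indicate a heterozygous call for line $i$ at
ordered SNP $j$ of a chromosome. The model assumes $K$ contiguous
segments, with $X_{ij} \sim \mathrm{Bernoulli}(p_k)$ inside segment $k$,
independent across cells; missing cells are excluded from both counts.
Because the likelihood pools all lines, a segment's sufficient statistics
are its pooled heterozygous and non-missing cell counts, and the
chromosome-level optimum for each $K$ is found by the classical
segment-cost dynamic program over SNP columns.

Two implementation points matter. First, the per-segment cost uses only
integer count sums, so $x\log x$ is tabulated once per chromosome and
the DP inner loop is pure table lookups. Second, the textbook
divide-and-conquer (split-monotonicity) speed-up is *invalid* here: with
heterogeneous per-column non-missing counts the Bernoulli segment cost
is not Monge, and we found counterexamples on random profiles. Instead
the package prunes DP candidates exactly: splitting a segment never
increases its cost, so a candidate $t$ with
$D_{k-1}(t) + c(t{+}1, j) \ge D_{k-1}(j)$ is dominated by $j$ forever
and can be discarded without changing the optimum. The pruned prefix DP
and the plain suffix DP are cross-checked on random profiles, and the
suffix DP is itself checked against exhaustive enumeration (with
leftmost-tie breakpoints) on 200 small random instances.

$K$ is selected by penalized likelihood with the Lebarbier-shaped
penalty $\mathrm{pen}(K) = K(1+\log(n/K))$; the constant is calibrated
by the slope heuristic (twice the regression slope of the
log-likelihood on $\mathrm{pen}(K)$ over the upper half of the fitted
$K$ range), with BIC available as an alternative. The exact criterion of
the original reference could not be reproduced from its description, so
the slope heuristic is the package's own calibrated default; its null
and recovery behavior (one segment on noise in at least 95% of runs;
a planted high-rate segment recovered as left/segment/right) is part of
the suite. `Kmax` defaults to `min(nSnps, 50)` per chromosome: on the
desk-scale profiles the package targets, optimal segmentations use far
fewer segments, and the full-path DP remains exact for any user-chosen
`Kmax`.

Each segment is then tested against the genome-wide rate $p_g$
(estimated as the pooled heterozygous fraction unless overridden) with
a one-sided exact binomial test on its pooled cells,
$p = P(X \ge k \mid n, p_g)$, followed by Benjamini-Hochberg control at
5%. Post-processing merges adjacent same-status segments, removes
single-SNP segments, re-merges, keeps segments of at least 5 SNPs, and
re-merges once more (without this last step the documented rule trace
"a short significant island between two non-significant neighbors
yields one merged segment" cannot hold); merged segments are re-tested
on pooled counts. Doubled-haploid validation re-tests each final
segment in a DH panel, where any heterozygosity is an alignment
artifact: segments significant in DHs are class 2
(structural-variant artifacts), the rest class 1 (inbreeding-depression
candidates), and segments with fewer than 5 DH SNPs are flagged
untestable.

# Diversity statistics with missing data

Heterozygous calls are treated as missing and all diversity statistics
use a haploid model — the lines are inbred, and residual heterozygotes
are both rare and the least reliable calls. With per-site non-missing
sample size $n_i$ and alternate count $k_i$:
$\pi = \sum_i 2k_i(n_i-k_i)/(n_i(n_i-1))$,
$\theta_W = \sum_{i \in \mathrm{seg}} 1/a_1(n_i)$, and Tajima's $D$
normalizes $\pi - \theta_W$ with the standard variance constants
evaluated at the mean per-site sample size rounded to an integer — a
documented approximation, as the exact variance under arbitrary
missingness patterns has no closed form. The site frequency spectrum is
projected to a common size $m$ by hypergeometric expectation
(deterministic, fractional mass; sites with fewer than $m$ genotypes
are skipped and monomorphic-class mass is dropped), folded when no
outgroup polarization is supplied.

The neutral calibration uses the package's own Hudson-style coalescent
sampler (no installed R package produces coalescent genotype matrices).
One caveat surfaced while validating it: at $n = 29$, $\theta = 50$ the
*finite-sample expectation of Tajima's D is about $-0.12$, not 0* — we
confirmed this independently with msprime — so a calibration band of
$\pm 0.05$ around zero for the mean of per-replicate $D$ is not
attainable by a correct implementation and the corresponding assertion
in the acceptance suite is expected to fail. $\pi$ and $\theta_W$ are
unbiased (within Monte-Carlo error, also at 30% missingness).

# Differential selection scan

Genic regions are gene bodies ±10 kb; control windows live >50 kb from
every gene and their lengths are drawn from the genic-region lengths.
Regions are analyzable with more than 7 SNPs and at most 30% missing
lines per group. Between two groups the package computes the
Weir-Cockerham variance-components Fst (haploid sample sizes,
ratio-of-sums across SNPs — appropriate for small groups), and within
each group Tajima's $D$. XP-CLR scores are *imported* from externally
produced window files, never recomputed; the synthetic generator
emulates such files with planted high-scoring windows.

Empirical p-values are the proportion of control regions at least as
extreme, with a $(r+1)/(n+1)$ pseudo-count so no p is exactly zero. A
gene is a differential-selection candidate when (1) its Fst empirical p
is below 5%, (2) its XP-CLR empirical p is below 5% in at least one
reciprocal direction, and (3) Tajima's $D$ is negative with empirical p
below 5% in at least one of the two groups. The expected false-positive
count is the fraction of controls passing all three thresholds times
the number of genes tested. One property of the synthetic world is
worth knowing: Balding-Nichols sites are independent draws with
ancestral frequencies bounded away from 0, so absolute $D$ values are
systematically positive and only the *relative* (control-calibrated)
tail identifies sweeps; planted sweeps must cover the full genic window
for the within-group $D$ clause to fire, and the bundled power tests do
exactly that.

# SUMSTAT network test

Per-gene Fst empirical p-values are mapped to $Z = \Phi^{-1}(1-p)$
(clamped to $[1/2N, 1-1/2N]$, $N$ the control count), then centred by
the median of an equal-occupancy SNP-count bin (20 bins by default,
bins under 5 genes merged) to remove the Z--SNP-count dependence. A
network's SUMSTAT is the sum of its genes' normalized Z; significance
comes from 1000 seeded resamples of equal-size gene sets drawn without
replacement from all scored genes, with $(1+\#\{ \ge \})/(R+1)$
smoothing. Networks sharing more than half their genes (overlap over
the smaller set) are merged into clusters by connected components.
Category enrichment of candidate lists is a one-sided Fisher test over
the annotated-gene universe with BH adjustment.

# f3 admixture test

For target $C$ and sources $A, B$:
$f_3 = \overline{(\hat c - \hat a)(\hat c - \hat b)} -
\overline{\hat c(1-\hat c)/(n_C - 1)}$, the second term removing the
bias from $C$'s finite haploid sample. The standard error is a
delete-one block jackknife over consecutive 25-SNP blocks (the block
convention used by Treemix-style analyses; configurable), and
$Z = f_3/\mathrm{SE}$ with $Z < -1.64$ significant at 5%. Under the
synthetic null ($A=B=C$ one population resampled) $Z$ is calibrated —
measured coverage of $|Z| < 1.64$ is ~0.91 — which means the "at least
90% inside the bounds" check is intrinsically borderline: it compares
an estimate of 0.90--0.91 against 0.90. The suite therefore uses 200
null replicates so the observed fraction estimates the truth instead of
flipping a small-sample coin.

# Synthetic data: what it does and does not emulate

The generators are first-class, seeded, and truth-emitting: binomial
read counts with Poisson depth and collapsed-paralog artifacts
(doubled depth, ~50/50 counts, unique-mapping fraction below 0.9);
Bernoulli heterozygosity profiles with planted segments; structured
haploid genotypes via Balding-Nichols frequencies (analytic Fst target)
with planted sweeps pushing frequencies toward fixation and optional
admixed groups $\alpha A + (1-\alpha)B$ plus residual drift; a neutral
coalescent for $\pi/\theta/D$ calibration; gene annotations with 50 kb
control buffers, gene networks with one optionally planted selected
network; and emulated XP-CLR score files. Missingness is independent
per cell at a configurable rate (default 0.25, matching the 18--32%
per-line regime of mid-depth data); the real missingness process is
unknown and certainly not independent, so tests passing under this
model say nothing about structured missingness. Likewise
Balding-Nichols sites are unlinked — there is no LD, no recombination
map, no demographic history — so LD-sensitive behavior (e.g. XP-CLR
itself) is out of reach by design, and sweep detection power here
reflects frequency shifts only.

Default study conditions follow the targeted panel scale: 57 lines,
mean depth 18, $\varepsilon = 0.01$, background heterozygosity 0.41%,
group sizes 13+14, Balding-Nichols $F = 0.15$. Where the scale is the
package's own choice (synthetic chromosome of 20000 SNPs at 200 bp
spacing; `Kmax = 15` for genome-scale segmentation runs; 50 null
replicates for FDR calibration; 1000-replicate coalescent calibration;
300 control windows per scan), it was chosen once as a realistic
desk-scale rendition and the suite runs at exactly these sizes.

# Numerical choices

Exact binomial tails are accumulated in log space via the shorter of
the two tails (log-sum-exp), never by subtracting near-unity CDFs.
DP tie-breaks are leftmost; the reconstruction tolerance is $10^{-9}$.
The pipeline (`runPipeline`) uses 0-based half-open coordinates
internally, converts at BED boundaries, validates its configuration
against unknown keys, derives all stage seeds from one global seed, and
is byte-identical across reruns of the same configuration. The
`pipeline` interface is the exported R functions themselves; there is
no shell wrapper, as the intended users drive analyses from R.

# Known limitations

* Tajima's D variance under missingness uses the mean-sample-size
  approximation; per-site exact variance is not implemented.
* The discrete-KS Poisson filter is conservative; its real level is
  below the nominal 5%.
* The slope-heuristic constant is calibrated on the upper half of the
  fitted K range and may be unstable when `Kmax` is very small; the
  fallback then prefers the smallest K within tolerance of the maximal
  likelihood.
* Control-window matching is by length only; matching by SNP count is
  not implemented (lengths and SNP counts are proportional in the
  synthetic genomes).
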