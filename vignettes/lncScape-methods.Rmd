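---
title: "Models and methods behind lncScape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lncScape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

lncScape profiles long non-coding RNA (lncRNA) expression in bulk RNA-seq
tumor cohorts and relates the lncRNA landscape to molecular subtype, the
coding transcriptome, promoter chromatin state and patient outcome. This
vignette explains the statistical models, the choices we made where the
procedure was genuinely open, and what the synthetic cohort used by the
test suite does and does not emulate.

## Quantification for a non-strand-specific library

All interval arithmetic lives in `GRanges`/`IRanges` objects (1-based,
closed), the containers the Bioconductor ecosystem standardizes on; GTF
and BED dialect conversions happen inside `rtracklayer` at the file
boundary, so no hand-rolled coordinate handling exists in the package.

Genes are quantified at the gene level: the exon model of a gene is the
union of all its annotated exons (`readGeneAnnotation()`), with the TSS
at the strand-aware 5' end of that union. Because a non-strand-specific
library cannot attribute a fragment that touches both an mRNA exon and a
lncRNA exon, counting follows the union rule (`unionCount()`): a
fragment counts for a gene only when that gene is the *only* gene whose
exons it overlaps, strand-blind. Consistently, the gene length used for
FPKM is the **masked length** (`maskedLengths()`): exonic bases not
overlapped by any exonic base of the other class (coding vs lncRNA).
Genes whose exons are entirely covered by the other class have no
defined FPKM and are excluded downstream.

$$\mathrm{FPKM}(g,s) = \frac{c_{gs} \cdot 10^9}{\ell_g \, N_s},$$

with $c_{gs}$ the union-mode count, $\ell_g$ the masked length in bases
and $N_s$ the per-sample total of counted fragments (upstream mapping
totals are not available at desk scale, so the column total is the
documented convention). The expressed set is defined by a prevalence
filter: FPKM $\ge 1$ in at least $\lceil 0.10\,n \rceil$ samples, both
thresholds inclusive.

Neighboring coding genes are assigned to lncRNAs with a local
basal-plus-extension rule (`assignNeighbors()`): each coding gene owns a
basal domain (5 kb upstream / 1 kb downstream of its TSS, strand-aware)
extended on each side up to 1 Mb from the TSS but stopping at the
nearest coding gene's basal domain; a lncRNA is assigned to every coding
gene whose domain contains its TSS. The association rule and its
parameters are exposed as arguments, since published analyses using
web-based region-enrichment services rarely state them.

## Normalization, testing, and the variance-stabilizing transform

Size factors are median-of-ratios (`estimateSizeFactors()`): the factor
of a sample is the median over genes (with positive geometric mean) of
the count divided by the gene's geometric mean. We take the arithmetic
median on the ratio scale — with an even number of usable genes this
differs from a log-scale median by the arithmetic/geometric gap of the
two middle ranks, a relative difference of order $10^{-4}$ in practice.

Differential expression uses a conditional negative-binomial exact test
(`nbExactTest()`). Dispersions come from a method-of-moments estimate on
normalized counts pooled within groups, an excess-variance trend
$\nu(\mu) = \mu + \alpha\mu^2$ fitted across genes by least squares of
the excess variance on $\mu^2$ (unbiased around the true $\alpha$, and
correctly near zero for Poisson data), and a working dispersion
$\max(\alpha_g, \hat\alpha)$ floored at $10^{-8}$. Given the two group
sums $K_A + K_B = K$, group sums are modeled as NB with means
proportional to the size-factor sums $S_A, S_B$ and size parameters
$S_A^2 / (\alpha \sum_{s \in A} f_s^2)$ (the exact size of a sum of
per-sample NB variables with common $\alpha$), and the p-value sums the
probabilities of all splits no more likely than the observed one,
normalized over the $K+1$ outcomes. Taking the *larger* of the per-gene
and trend dispersion makes the test slightly conservative when per-gene
estimates are noisy (few samples per group); with $\gtrsim 100$ samples
per group the empirical size matches the nominal level. This is a
reimplementation of the classical exact-test approach, not a
bit-compatible clone of any released package; the released packages
serve as independent cross-checks in the test suite.

Subtype markers (`subtypeMarkers()`) are one-vs-rest contrasts with fold
change computed on normalized means with a pseudocount of 1 (fold
change is undefined at zero mean), thresholds FC $\ge 2$ and BH
FDR $< 0.05$.

The VST uses the closed antiderivative of $1/\sqrt{\nu(\mu)}$, namely
$(2/\sqrt{\alpha})\,\mathrm{asinh}\sqrt{\alpha\mu}$ — the integral the
mean-variance trend defines has an exact form, so numerical quadrature
would only add error — calibrated affinely so that value and slope agree
with $\log_2$ at the 99th-percentile normalized count. When the fitted
trend is non-positive the Poisson-limit transform $2\sqrt{x}$ is used,
with a message.

## Consensus clustering and the number of subtypes

`runConsensus()` performs 500 perturbed clusterings: each run draws 80%
of samples and 80% of features without replacement and clusters the
subsample hierarchically with Pearson distance ($1-r$) and Ward linkage
(the classical update on squared dissimilarities; `hclust`'s
`"ward.D2"`). The consensus of a pair is the fraction of co-clustered
runs *among co-sampled runs*, so rarely drawn pairs are not biased low;
never-co-sampled pairs fall back to 0 with a logged count. The number of
clusters inside each run equals the k under evaluation. Per-run RNG
seeds are `seed + run`, making the matrix bit-reproducible; the final
partition clusters the consensus rows with Euclidean distance and Ward
linkage.

The number of subtypes is chosen by BIC over a hard-assignment spherical
Gaussian mixture (`selectK()`):
$\mathrm{BIC}(k) = n d \log(2\pi\hat\sigma^2) + nd + (kd + 1)\log n$
with $\hat\sigma^2$ the pooled within-cluster variance over all $d$
features. The open design question is which feature space to score. We
score the expression matrix itself (samples as points, labels from the
full consensus pipeline at each k): it is the *same* space for every k,
so the criteria are comparable. Scoring each k's own consensus-row space
(selectable via `space = "consensus"`) compares likelihoods across
different data and, in our simulations of well-separated clusters,
frequently prefers a merged solution; it is retained only as an
alternative. Degenerate singleton clusters are scored with the pooled
variance and flagged.

## Association maps and per-lncRNA enrichment

The lncRNA-mRNA association map is the Pearson correlation matrix on
VST-scale expression (the scale is a documented choice; correlations are
invariant to the affine calibration of the VST), ternarized at the
global 1% tails: the $\lfloor 0.01N \rfloor$ largest entries become +1,
the same number of smallest entries −1, the rest 0, with ties broken by
ascending (row, column) index and positives assigned first (relevant
only for degenerate constant matrices, which are flagged). Two-way
hierarchical clustering (Euclidean, complete) orders the map for
display.

`gseaScreen()` treats each lncRNA as a continuous phenotype: mRNAs are
ranked by their correlation with the lncRNA profile and a weighted
Kolmogorov–Smirnov running sum is computed per gene set — in-set genes
add $|r|^p / N_R$, others subtract $1/(N - N_H)$, and the enrichment
score is the extremum, sign retained ($p = 1$ by default). Because the
phenotype is continuous, sample-label permutation is unavailable; the
null distribution instead permutes gene labels (random sets of the same
size on the same ranked list, shared across equal-sized sets within a
phenotype). NES divides the observed score by the mean absolute null
score of matching sign; a sign-specific permutation p-value gets BH
adjustment across all (lncRNA, set) pairs, and the ternary call is
$\mathrm{sign}(\mathrm{NES})$ at FDR $< 0.05$, else 0. Biclustering of
the ternary NES matrix reports maximal constant-sign blocks above a
configurable minimum size, found by scanning row/column tree cuts.
Hypergeometric enrichment of neighbor-gene lists against a stated
universe (`neighborSetEnrichment()`) stands in for web-based pathway
annotation of lncRNA neighborhoods.

## Promoter chromatin state

A gene is "marked" when any ChIP-seq peak overlaps (by $\ge 1$ base) the
closed window $[\mathrm{TSS} - 5\,\mathrm{kb}, \mathrm{TSS} +
5\,\mathrm{kb}]$ — total width $10\,\mathrm{kb} + 1$; whether published
analyses require the peak center or any overlap in such windows is
usually unstated, so any-overlap is the default and the window is an
argument. Derived calls: bivalent = H3K4me3 and H3K27me3 in one context;
enhancer lncRNA = H3K27ac in at least one context (lax) or H3K27ac plus
H3K4me2 in a single stated context (stringent); mark gain/loss
partitions the genes marked in either of two cell contexts. Peaks are
used as released, without score filtering.

## Survival

`kmLogrank()` wraps the product-limit estimator and the k-group log-rank
test from the survival package. The per-gene screen `coxScreen()` fits a
univariate proportional-hazards model per gene (continuous covariate,
Breslow ties) and applies BH across the full screened list; constant
covariates get coefficient exactly 0 with p = 1, non-converging fits are
flagged with p = 1. Kaplan-Meier figures per gene use a median split
with ties to "low", since the cutpoint convention behind published
per-gene KM curves is rarely stated.

## The synthetic cohort: what it emulates, and what it does not

`cohortConfig()` defaults define the study conditions: 200 samples in 4
latent subtypes with proportions 0.46/0.25/0.19/0.10 (echoing the
luminal-A/luminal-B/basal/HER2 mixture of breast-cancer series), 800
mRNAs and 300 lncRNAs, NB dispersion 0.2, 25 lncRNA + 50 mRNA markers
per subtype at $\log_2$ effect 2 (four-fold), 40 cis pairs at latent
correlation 0.8, 15% of lncRNAs with mRNA-overlapping exons, bivalent
fraction 0.1, enhancer fraction 0.6, H3K27me3 loss fraction 0.5 between
the two cell contexts, exponential survival with subtype hazard ratios
(1, 1.5, 0.6, 1.2) and 10 prognostic lncRNAs at log-hazard 0.5, 30%
censoring. A third of the lncRNAs are drawn quiescent ($\log_2$ baseline
−7 to −3.5) so the prevalence filter has something to remove; planted
markers, cis and prognostic genes are kept above that range, because
they model the *expressed* landscape a study screens.

Counts are NB with $\log_2$ mean = gene baseline + subtype effect +
shared cis factor + $N(0, 0.25^2)$ biological noise, scaled by 4×-range
library sizes. The cis factor is scaled so the **observed** log-scale
correlation approaches the target: the scaling accounts for the
biological noise and for the delta-method NB noise variance
$(1/\mu + \alpha)/\ln^2 2$, so empirical correlations of planted pairs
land within ±0.1 of the target at large n.

The prognostic lncRNAs form a co-expressed module: one latent
per-patient risk score with hazard multiplier $\exp(0.5 z)$, tracked by
the 10 genes with gene-module $r^2 = 0.8$ and module SD 1.2 $\log_2$
units. Ten *independent* hazards of that size would attenuate each
other's marginal coefficients (omitted-covariate frailty) to the point
of undetectability; a module matches both the biology (prognostic
signatures are co-expressed programs) and the marginal effect the screen
estimates. At the default n = 200 the per-gene screen sits near its
power boundary (planted-gene FDRs straddle 0.05 depending on the seed);
at n = 300 it recovers 8–10 of 10.

Chromatin truth couples mark probabilities to expression tertiles
(active marks frequent at high expression, H3K27me3/H3K9me3 the
reverse), plants the bivalent and enhancer fractions exactly, and
removes H3K27me3 in the second context for the configured fraction of
marked genes with loss biased toward higher-expressed genes — the data
model has one tumor-cohort expression matrix, not per-cell-line
expression, so "derepressed after loss" is expressed through that bias.
Every marked gene's peak is placed on a per-gene promoter zone that lies
inside its own ±5 kb window and outside every other gene's window, so
annotation recovers the planted truth exactly; genes with no such zone
are forced unmarked everywhere, keeping gain/loss partitions consistent.

What the generator does **not** emulate: read-level artifacts (mapping
error, positional bias, duplicates), isoform switching within genes,
copy-number-driven expression, correlated gene-gene networks beyond the
planted cis pairs and prognostic module, batch effects, or non-peak
chromatin signal. Passing tests therefore demonstrate that the
implementations are correct and that the pipeline recovers planted
structure under NB noise at realistic sizes — not that any biological
conclusion transfers to a particular real cohort.

## Numerical conventions and problem sizes

Ternarization tails use `floor` and global quantiles; BH keeps input
order; Ward on the non-Euclidean $1-r$ distance uses the classical
squared-distance update; hierarchical merge ties follow `hclust`'s
convention (ties have measure zero for continuous expression data — the
naive-agglomeration oracle in the tests checks merge heights and
partitions on random data). All resampling procedures take explicit
seeds, restore the caller's RNG state, and are bit-reproducible. The
test suite exercises the full pipeline at 40–200 samples and the
consensus engine at the default 500 runs; the k-selection study uses 20
replicate cohorts of 60 samples with balanced subtypes, the NB null
calibration 1000 genes at 100 samples per group, and the survival
recovery study 300 samples — sizes chosen so each property is tested at
the scale where its statistical guarantee applies.
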