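# lncScape

Long non-coding RNAs (lncRNAs) are largely invisible to classical
expression arrays, yet bulk RNA-seq cohorts carry enough signal to
profile them genome-wide — if the quantification respects that standard
libraries are non-strand-specific, so reads falling where lncRNA and
mRNA exons overlap cannot be attributed to either gene. lncScape
implements that landscape analysis for tumor cohorts end to end:

* **Overlap-aware quantification** — gene-level exon unions from GTF,
  union-mode fragment counting (ambiguous fragments discarded), and
  FPKM on the *non-overlapped* exonic length
  `FPKM(g,s) = c(g,s)·10⁹ / (ℓ_masked(g)·N(s))`, with the expressed set
  defined by FPKM ≥ 1 in at least 10% of samples.
* **Subtype discovery** — consensus clustering: 500 runs of
  hierarchical clustering (Pearson distance 1−r, Ward linkage) on
  resampled data (80% of samples, 80% of lncRNAs per run), co-cluster
  frequencies averaged over co-sampling, the consensus matrix clustered
  (Euclidean, Ward), and the number of subtypes chosen by BIC.
* **Differential expression** — median-of-ratios size factors, a
  conditional negative-binomial exact test with method-of-moments +
  trend dispersions, Benjamini–Hochberg FDR, and one-vs-rest subtype
  markers at fold change ≥ 2, FDR < 0.05.
* **lncRNA–mRNA association** — Pearson correlation matrices on
  variance-stabilized counts, ternarized at the global 1% tails
  (−1/0/+1), two-way clustering; basal-plus-extension assignment of
  lncRNAs to neighboring coding genes and a cis-correlation report.
* **Per-lncRNA GSEA** — each lncRNA is a continuous phenotype; mRNAs
  are ranked by correlation, scored by the weighted Kolmogorov–Smirnov
  running sum, normalized against gene-label permutations (NES), and
  ternarized at FDR < 0.05; biclustering finds constant-sign blocks.
* **Promoter chromatin state** — a gene is marked when a ChIP-seq peak
  overlaps the closed ±5 kb window around its TSS; derived calls for
  bivalency (H3K4me3 + H3K27me3), enhancer lncRNAs (H3K27ac, optionally
  + H3K4me2), and mark gain/loss between two cell contexts.
* **Survival** — Kaplan–Meier curves with the k-group log-rank test
  between subtypes, and a per-gene univariate Cox screen (Breslow ties)
  with BH FDR.
* **A ground-truth synthetic cohort** — `cohortConfig()` /
  `generateAnnotation()` / `generateCohort()` / `generatePeaks()` emit
  GTF, counts, clinical tables, BED peaks and GMT gene sets with every
  planted structure (subtypes, markers, cis pairs, chromatin truth,
  prognostic module) known exactly, so the whole pipeline runs and is
  validated with no external data.

`runPipeline()` orchestrates the stages (quantify → filter → normalize →
cluster → markers → associate → gsea → chromatin → survive), writes one
TSV per result plus a `manifest.json`, and is byte-identical across
reruns with the same seed.

## Worked example

```r
library(lncScape)
cfg <- cohortConfig(nSamples = 60, nMrna = 200, nLnc = 120,
                    nMarkerLnc = 12, nMarkerMrna = 20, nCisPairs = 10,
                    nPrognostic = 4, seed = 42)
ann <- generateAnnotation(cfg)
ann$geneModel
#> GeneModel with 320 genes on 2 sequence(s)
#>   protein_coding: 200  lncRNA: 120
#>   biotypes: antisense=10, lincRNA=66, processed_transcript=25, ...

coh  <- generateCohort(cfg, ann)
lengths <- maskedLengths(ann$geneModel)
fpkm <- computeFpkm(coh$counts[lengths$gene_id[lengths$masked_length > 0], ],
                    lengths)
expressed <- filterLowExpression(fpkm)        # FPKM >= 1 in >= 10%
lnc <- expressed[isLncRNA(ann$geneModel)[expressed]]
length(lnc)
#> [1] 97
```

Of the 120 simulated lncRNAs, 97 pass the expression filter (the
generator draws about a third of them quiescent). Clustering the
variance-stabilized lncRNA profiles:

```r
sf  <- estimateSizeFactors(coh$counts[expressed, ])
disp <- fitDispersions(coh$counts[expressed, ], sf, rep("all", 60))
vst <- vstTransform(coh$counts[expressed, ], sf, disp)
cm  <- runConsensus(vst[lnc, ], k = 4, nRuns = 500, seed = 1)
cm
#> ConsensusMatrix: 60 samples, 500 runs at k = 4
#>   off-diagonal consensus: median 0.012  range [ 0 , 1 ]
subtype <- clusterConsensus(cm, 4)
table(subtype, coh$truth$cluster)
#> subtype  1  2  3  4
#>       1  0 15  0  0
#>       2  0  0  0  5
#>       3 32  0  0  0
#>       4  0  0  8  0
```

The near-binary consensus values (median 0.012 off-diagonal, 1 within
blocks) and the contingency table show the planted four-subtype
structure recovered exactly (labels permuted, as expected). Markers of
subtype 1 and the subtype survival contrast:

```r
markers <- subtypeMarkers(coh$counts[expressed, ], sf, subtype, 1)
head(markers[, c("gene_id", "fold_change", "fdr")], 3)
#>      gene_id fold_change          fdr
#> 57  MRNA0037    5.097135 3.024761e-15
#> 127 MRNA0090    4.776898 5.080346e-15
#> 45  MRNA0028    4.607733 4.497069e-14

km <- kmLogrank(subtype, coh$clinical)
signif(km$p, 3)
#> [1] 0.0109
```

The top markers are planted four-fold genes (fold changes near 4–5 with
tiny FDRs), and the log-rank test detects the subtype-dependent hazards
(p ≈ 0.011 at n = 60).

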