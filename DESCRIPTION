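Package: lncScape
Title: lncRNA Landscape Profiling, Consensus Subtyping and Integrative
    Annotation for Tumor RNA-Seq Cohorts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to profile long non-coding RNA (lncRNA) expression in
    bulk RNA-seq tumor cohorts and relate it to molecular subtype, the
    coding transcriptome, promoter chromatin state and patient outcome.
    Implements overlap-masked gene lengths and union-mode fragment
    counting for non-strand-specific libraries, FPKM on non-overlapped
    exon length with a prevalence-based expression filter,
    median-of-ratios normalization with a negative-binomial exact test
    and variance-stabilizing transform, resampled hierarchical consensus
    clustering with BIC-guided choice of the number of subtypes,
    ternarized lncRNA-mRNA correlation maps, per-lncRNA gene-set
    enrichment with permutation-based normalized scores, histone-mark
    annotation of transcription start sites (bivalency, enhancer marks,
    mark gain/loss between cell contexts), Kaplan-Meier/log-rank and
    per-gene Cox survival screens, and a ground-truth synthetic cohort
    generator that exercises the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    survival,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    DESeq2,
    withr
biocViews: Transcriptomics, GeneExpression, Clustering, Survival,
    Epigenetics, RNASeq
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'association.R'
    'chromatin.R'
    'consensus.R'
    'expression.R'
    'gene-model.R'
    'gsea.R'
    'io.R'
    'lncScape-package.R'
    'normalization.R'
    'pipeline.R'
    'survival.R'
    'synthetic-data.R'
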