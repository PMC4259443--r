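#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList reduce findOverlaps
#'   strand start end width seqnames
#' @importFrom IRanges IRanges
NULL

.LNC_BIOTYPES <- c("antisense", "lincRNA", "sense_overlapping",
                   "sense_intronic", "processed_transcript",
                   "three_prime_overlapping_ncRNA")
.ALL_BIOTYPES <- c("protein_coding", .LNC_BIOTYPES)

#' Gene-level annotation model
#'
#' A `GeneModel` holds one record per gene: its merged exon structure, the
#' strand-aware transcription start site (TSS), and a biotype that is either
#' `protein_coding` or one of the six lncRNA categories (antisense, lincRNA,
#' sense overlapping, sense intronic, processed transcript, 3'-overlapping
#' ncRNA). Genes are quantified at the gene level, so the exon model is the
#' per-gene union of all annotated exons.
#'
#' @slot genes A [GenomicRanges::GRanges] with one range per gene (the gene
#'   span) and metadata columns `gene_id`, `gene_name`, `biotype`, `tss`.
#' @slot exons A [GenomicRanges::GRangesList], parallel to `genes`, of merged
#'   (non-overlapping, sorted) exons per gene.
#' @export
setClass("GeneModel",
         slots = c(genes = "GRanges", exons = "CompressedGRangesList"))

setValidity("GeneModel", function(object) {
    g <- object@genes
    msg <- character()
    need <- c("gene_id", "gene_name", "biotype", "tss")
    if (!all(need %in% colnames(mcols(g))))
        return(paste("genes must carry metadata columns:",
                     paste(need, collapse = ", ")))
    if (anyDuplicated(g$gene_id))
        msg <- c(msg, "duplicated gene_id")
    if (!all(g$biotype %in% .ALL_BIOTYPES))
        msg <- c(msg, "unknown biotype")
    if (length(object@exons) != length(g) ||
        !identical(names(object@exons), g$gene_id))
        msg <- c(msg, "exons must be named by and parallel to gene_id")
    if (any(lengths(object@exons) == 0L))
        msg <- c(msg, "every gene needs at least one exon")
    red <- reduce(object@exons)
    if (!identical(unname(lengths(red)), unname(lengths(object@exons))))
        msg <- c(msg, "exons must be merged (pairwise non-overlapping)")
    expect_tss <- ifelse(as.character(strand(g)) == "-",
                         max(end(object@exons)), min(start(object@exons)))
    if (!all(g$tss == expect_tss))
        msg <- c(msg, "tss must be the strand-aware 5' end of the exon union")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Consensus co-clustering matrix
#'
#' Pairwise co-clustering frequencies over resampled clustering runs:
#' `M[i, j]` is the fraction of runs in which samples i and j were assigned
#' to the same cluster, among the runs in which both were drawn. Pairs never
#' co-sampled are set to 0 (and counted); the diagonal is forced to 1.
#'
#' @slot M Numeric symmetric matrix in \[0, 1\] with unit diagonal.
#' @slot coSampled Integer symmetric matrix of co-sampling counts.
#' @slot nRuns Number of resampling runs.
#' @slot k Number of clusters used inside each run.
#' @export
setClass("ConsensusMatrix",
         slots = c(M = "matrix", coSampled = "matrix",
                   nRuns = "integer", k = "integer"))

setValidity("ConsensusMatrix", function(object) {
    M <- object@M
    msg <- character()
    if (nrow(M) != ncol(M)) msg <- c(msg, "M must be square")
    if (!isTRUE(all.equal(M, t(M)))) msg <- c(msg, "M must be symmetric")
    if (any(M < 0 | M > 1)) msg <- c(msg, "M entries must lie in [0, 1]")
    if (any(diag(M) != 1)) msg <- c(msg, "diag(M) must equal 1")
    if (!identical(dim(M), dim(object@coSampled)))
        msg <- c(msg, "coSampled must match dim(M)")
    if (!isTRUE(all.equal(object@coSampled, t(object@coSampled))))
        msg <- c(msg, "coSampled must be symmetric")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Ternary association matrix
#'
#' Association matrix on the ternary scale \{-1, 0, +1\}, as produced by
#' [ternarize()] (tail-quantile cut of a correlation matrix) or by the
#' FDR/NES rule of the gene-set enrichment screen.
#'
#' @slot entries Integer matrix with values in \{-1, 0, 1\}; dimnames carry
#'   the row (lncRNA) and column (mRNA or gene-set) identifiers.
#' @slot tail Tail fraction used for the cut (`NA` for FDR/NES mode).
#' @export
setClass("TernaryMatrix",
         slots = c(entries = "matrix", tail = "numeric"))

setValidity("TernaryMatrix", function(object) {
    e <- object@entries
    if (!all(e %in% c(-1L, 0L, 1L)))
        return("entries must be -1, 0 or 1")
    TRUE
})

#' Histone-mark annotation of gene promoters
#'
#' A boolean gene x mark x cell-context array: `TRUE` when a ChIP-seq peak
#' for that mark, in that context, falls within the promoter window around
#' the gene's TSS (see [annotateMarks()]).
#'
#' @slot marked Three-dimensional logical array with dimnames
#'   `(gene_id, mark, context)`; defined for every triple.
#' @slot window Half-width of the promoter window in bases.
#' @export
setClass("MarkAnnotation",
         slots = c(marked = "array", window = "numeric"))

setValidity("MarkAnnotation", function(object) {
    a <- object@marked
    if (length(dim(a)) != 3L) return("marked must be a 3-d array")
    if (!is.logical(a)) return("marked must be logical")
    if (is.null(dimnames(a)) || any(vapply(dimnames(a), is.null, TRUE)))
        return("marked must have complete dimnames (gene, mark, context)")
    TRUE
})
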