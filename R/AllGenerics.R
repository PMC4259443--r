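#' @include AllClasses.R
NULL

#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @export
setGeneric("geneBiotypes", function(x) standardGeneric("geneBiotypes"))

#' @export
setGeneric("isLncRNA", function(x) standardGeneric("isLncRNA"))

#' @export
setGeneric("tssPositions", function(x) standardGeneric("tssPositions"))

#' @export
setGeneric("exonsByGene", function(x) standardGeneric("exonsByGene"))

#' @export
setGeneric("consensusValues", function(x) standardGeneric("consensusValues"))

#' @export
setGeneric("coSampledCounts", function(x) standardGeneric("coSampledCounts"))

#' @export
setGeneric("ternaryEntries", function(x) standardGeneric("ternaryEntries"))

#' @export
setGeneric("isMarked", function(x, mark, context) standardGeneric("isMarked"))

#' Accessors for GeneModel
#'
#' @param x A [GeneModel-class] object.
#' @return `geneIds`: character vector of gene identifiers. `geneBiotypes`:
#'   named character vector of biotypes. `isLncRNA`: named logical, `TRUE`
#'   for every biotype other than `protein_coding`. `tssPositions`: a
#'   `GRanges` of width-1 TSS positions. `exonsByGene`: the merged exon
#'   `GRangesList`.
#' @name GeneModel-accessors
#' @aliases geneIds geneBiotypes isLncRNA tssPositions exonsByGene
NULL

#' @rdname GeneModel-accessors
#' @export
setMethod("geneIds", "GeneModel", function(x) x@genes$gene_id)

#' @rdname GeneModel-accessors
#' @export
setMethod("geneBiotypes", "GeneModel", function(x)
    stats::setNames(x@genes$biotype, x@genes$gene_id))

#' @rdname GeneModel-accessors
#' @export
setMethod("isLncRNA", "GeneModel", function(x)
    stats::setNames(x@genes$biotype != "protein_coding", x@genes$gene_id))

#' @rdname GeneModel-accessors
#' @export
setMethod("tssPositions", "GeneModel", function(x) {
    g <- x@genes
    GRanges(seqnames(g), IRanges(g$tss, width = 1L), strand = strand(g),
            gene_id = g$gene_id)
})

#' @rdname GeneModel-accessors
#' @export
setMethod("exonsByGene", "GeneModel", function(x) x@exons)

#' @describeIn GeneModel-accessors Subset a GeneModel by index, gene id or
#'   logical vector.
#' @param i index, gene ids, or logical vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "GeneModel", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@genes$gene_id)
    new("GeneModel", genes = x@genes[i], exons = x@exons[i])
})

#' @export
setMethod("length", "GeneModel", function(x) length(x@genes))

setMethod("show", "GeneModel", function(object) {
    bt <- table(object@genes$biotype)
    cat("GeneModel with", length(object@genes), "genes on",
        length(unique(as.character(seqnames(object@genes)))),
        "sequence(s)\n")
    cat("  protein_coding:", sum(object@genes$biotype == "protein_coding"),
        " lncRNA:", sum(object@genes$biotype != "protein_coding"), "\n")
    cat("  biotypes:", paste(names(bt), bt, sep = "=", collapse = ", "), "\n")
})

#' Accessors for ConsensusMatrix
#'
#' @param x A [ConsensusMatrix-class].
#' @return `consensusValues`: the numeric consensus matrix;
#'   `coSampledCounts`: the integer co-sampling count matrix.
#' @name ConsensusMatrix-accessors
NULL

#' @rdname ConsensusMatrix-accessors
#' @export
setMethod("consensusValues", "ConsensusMatrix", function(x) x@M)

#' @rdname ConsensusMatrix-accessors
#' @export
setMethod("coSampledCounts", "ConsensusMatrix", function(x) x@coSampled)

setMethod("show", "ConsensusMatrix", function(object) {
    cat("ConsensusMatrix:", nrow(object@M), "samples,",
        object@nRuns, "runs at k =", object@k, "\n")
    off <- object@M[upper.tri(object@M)]
    cat("  off-diagonal consensus: median", round(stats::median(off), 3),
        " range [", round(min(off), 3), ",", round(max(off), 3), "]\n")
})

#' Accessor for TernaryMatrix
#'
#' @param x A [TernaryMatrix-class].
#' @return Integer matrix of -1/0/+1 entries.
#' @export
#' @name ternaryEntries
setMethod("ternaryEntries", "TernaryMatrix", function(x) x@entries)

setMethod("show", "TernaryMatrix", function(object) {
    e <- object@entries
    cat("TernaryMatrix:", nrow(e), "x", ncol(e),
        sprintf(" (+1: %d, -1: %d, 0: %d)\n",
                sum(e == 1L), sum(e == -1L), sum(e == 0L)))
})

#' Query a MarkAnnotation
#'
#' @param x A [MarkAnnotation-class].
#' @param mark Histone mark name (e.g. `"H3K4me3"`).
#' @param context Cell context name.
#' @return Named logical vector over genes.
#' @export
#' @name isMarked
setMethod("isMarked", "MarkAnnotation", function(x, mark, context) {
    out <- x@marked[, mark, context]
    stats::setNames(as.logical(out), dimnames(x@marked)[[1L]])
})

#' @describeIn isMarked Dimension names of the annotation array:
#'   `list(gene, mark, context)`.
#' @export
setMethod("dimnames", "MarkAnnotation", function(x) dimnames(x@marked))

setMethod("show", "MarkAnnotation", function(object) {
    d <- dim(object@marked)
    cat("MarkAnnotation:", d[1L], "genes x", d[2L], "marks x", d[3L],
        "contexts (window +/-", object@window, "bp)\n")
    cat("  marks:", paste(dimnames(object@marked)[[2L]], collapse = ", "),
        "\n  contexts:",
        paste(dimnames(object@marked)[[3L]], collapse = ", "), "\n")
})
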