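#' @include AllClasses.R
NULL

.HISTONE_MARKS <- c("H3K4me3", "H3K4me2", "H3K36me3", "H3K27ac",
                    "H3K27me3", "H3K9me3")

#' Read a ChIP-seq peak set from BED
#'
#' Only the first three BED columns are required. The mark and cell
#' context are recorded in the object metadata for [annotateMarks()].
#'
#' @param path BED file path.
#' @param mark Histone mark name.
#' @param context Cell context (e.g. `"HMEC"`, `"MCF7"`).
#' @return A `GRanges` of peaks with `metadata()$mark` / `$context`.
#' @export
readPeakBed <- function(path, mark, context) {
    gr <- rtracklayer::import(path, format = "BED")
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    metadata(gr)$mark <- mark
    metadata(gr)$context <- context
    gr
}

#' Annotate gene promoters with histone marks
#'
#' A gene is marked when any peak for a mark/context overlaps (by at least
#' one base) the closed promoter window `[tss - window, tss + window]`
#' around the gene's strand-aware TSS -- a window of total width
#' `2 * window + 1`. Peaks on chromosomes absent from the annotation are
#' counted and reported in a message.
#'
#' @param gm A [GeneModel-class].
#' @param peaks A list of peak `GRanges` as returned by [readPeakBed()]
#'   (every (mark, context) combination found defines the annotation
#'   dimensions).
#' @param window Half-width of the promoter window in bases (default
#'   5000).
#' @return A [MarkAnnotation-class].
#' @export
annotateMarks <- function(gm, peaks, window = 5000) {
    marks <- unique(vapply(peaks, function(p) metadata(p)$mark, ""))
    contexts <- unique(vapply(peaks, function(p) metadata(p)$context, ""))
    ids <- geneIds(gm)
    tssGr <- tssPositions(gm)
    win <- GRanges(seqnames(tssGr),
                   IRanges(pmax(1L, start(tssGr) - window),
                           start(tssGr) + window))
    a <- array(FALSE, dim = c(length(ids), length(marks), length(contexts)),
               dimnames = list(ids, marks, contexts))
    unmatched <- 0L
    chrs <- unique(as.character(seqnames(win)))
    for (p in peaks) {
        mk <- metadata(p)$mark; cx <- metadata(p)$context
        unmatched <- unmatched +
            sum(!(as.character(seqnames(p)) %in% chrs))
        ## seqlevel mismatches are legitimate here (reported via the
        ## unmatched-peak count), so silence the combine warning
        ov <- suppressWarnings(findOverlaps(win, p, ignore.strand = TRUE))
        a[unique(S4Vectors::queryHits(ov)), mk, cx] <- TRUE
    }
    if (unmatched > 0L)
        message(unmatched, " peak(s) on chromosomes absent from the ",
                "annotation; left unmarked")
    new("MarkAnnotation", marked = a, window = window)
}

#' Bivalent genes in a cell context
#'
#' Genes carrying both the activating H3K4me3 and the repressive H3K27me3
#' mark at their promoter -- the poised "bivalent" chromatin state.
#'
#' @param ann A [MarkAnnotation-class].
#' @param context Cell context name.
#' @return Character vector of bivalent gene ids.
#' @export
bivalentGenes <- function(ann, context) {
    both <- isMarked(ann, "H3K4me3", context) &
        isMarked(ann, "H3K27me3", context)
    names(both)[both]
}

#' Enhancer-associated lncRNAs
#'
#' In the lax mode, a gene qualifies when its promoter carries H3K27ac in
#' *any* of the given contexts. In the stringent mode an enhancer requires
#' both H3K27ac and H3K4me2 in one single stated context.
#'
#' @param ann A [MarkAnnotation-class].
#' @param contexts Contexts considered (lax mode may give several;
#'   stringent mode requires exactly one).
#' @param stringent Logical; see Details.
#' @param genes Optional subset of gene ids (e.g. the expressed lncRNAs).
#' @return Character vector of qualifying gene ids.
#' @export
enhancerLncRNAs <- function(ann, contexts, stringent = FALSE,
                            genes = NULL) {
    if (stringent) {
        if (length(contexts) != 1L)
            stop("stringent mode requires a single context")
        hit <- isMarked(ann, "H3K27ac", contexts) &
            isMarked(ann, "H3K4me2", contexts)
    } else {
        hit <- Reduce(`|`, lapply(contexts, function(cx)
            isMarked(ann, "H3K27ac", cx)))
    }
    out <- names(hit)[hit]
    if (!is.null(genes)) out <- intersect(out, genes)
    out
}

#' Mark gain/loss between two cell contexts
#'
#' Partitions the genes marked in either context into those that lost the
#' mark (marked in `contextA` only), gained it (`contextB` only) or
#' retained it (both).
#'
#' @param ann A [MarkAnnotation-class].
#' @param mark Histone mark.
#' @param contextA,contextB The two contexts compared.
#' @return List of character vectors `lost`, `gained`, `retained`.
#' @export
markChange <- function(ann, mark, contextA, contextB) {
    a <- isMarked(ann, mark, contextA)
    b <- isMarked(ann, mark, contextB)
    list(lost = names(a)[a & !b],
         gained = names(a)[!a & b],
         retained = names(a)[a & b])
}

#' Expression summaries by histone mark
#'
#' Groups genes by each mark in a context and summarizes the distribution
#' of per-gene median expression: the classic read-out that active marks
#' accompany high expression while H3K27me3/H3K9me3 accompany low.
#'
#' @param expr Expression matrix (genes x samples), e.g. FPKM.
#' @param ann A [MarkAnnotation-class].
#' @param context Cell context.
#' @return `data.frame` with `mark`, `n`, `q1`, `median`, `q3` (per-gene
#'   median expression of the marked genes; `n = 0` rows carry `NA`s).
#' @export
expressionByMark <- function(expr, ann, context) {
    med <- apply(expr, 1L, stats::median)
    marks <- dimnames(ann)[[2L]]
    rows <- lapply(marks, function(mk) {
        hit <- isMarked(ann, mk, context)
        g <- intersect(names(hit)[hit], names(med))
        if (!length(g))
            return(data.frame(mark = mk, n = 0L, q1 = NA_real_,
                              median = NA_real_, q3 = NA_real_,
                              stringsAsFactors = FALSE))
        q <- stats::quantile(med[g], c(0.25, 0.5, 0.75), names = FALSE)
        data.frame(mark = mk, n = length(g), q1 = q[1L], median = q[2L],
                   q3 = q[3L], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Rank-sum comparison of expression between two mark groups
#'
#' Two-sided Wilcoxon rank-sum test of per-gene median expression between
#' the genes marked by `markX` and those marked by `markY` in a context.
#'
#' @inheritParams expressionByMark
#' @param markX,markY The two marks compared.
#' @return List with `p_value` and the group sizes.
#' @export
compareMarkExpression <- function(expr, ann, context, markX, markY) {
    med <- apply(expr, 1L, stats::median)
    gx <- intersect(names(which(isMarked(ann, markX, context))), names(med))
    gy <- intersect(names(which(isMarked(ann, markY, context))), names(med))
    if (!length(gx) || !length(gy))
        return(list(p_value = NA_real_, nX = length(gx), nY = length(gy)))
    list(p_value = stats::wilcox.test(med[gx], med[gy])$p.value,
         nX = length(gx), nY = length(gy))
}
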