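#' @include AllClasses.R
NULL

#' Union-mode fragment counting
#'
#' Counts sequenced fragments against gene-level exon unions under the
#' "union" rule for a non-strand-specific library: a fragment is counted
#' for gene g if and only if g is the *only* gene whose exons it overlaps
#' (any overlap, strand-blind). Ambiguous fragments -- in particular any
#' fragment touching both a coding and a lncRNA exon -- are discarded, as
#' are fragments overlapping no exon.
#'
#' @param fragments A [GenomicRanges::GRanges] of aligned fragments.
#' @param gm A [GeneModel-class].
#' @return Named integer vector of counts, one per gene (a count-matrix
#'   column).
#' @export
unionCount <- function(fragments, gm) {
    counts <- stats::setNames(integer(length(gm)), geneIds(gm))
    if (length(fragments) == 0L) return(counts)
    hits <- findOverlaps(fragments, exonsByGene(gm), ignore.strand = TRUE)
    if (length(hits) == 0L) return(counts)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ## a GRangesList subject yields one hit per (fragment, gene); dedupe
    ## defensively anyway
    key <- !duplicated(paste(qh, sh))
    qh <- qh[key]; sh <- sh[key]
    ngene <- tabulate(qh, nbins = length(fragments))
    keep <- qh %in% which(ngene == 1L)
    tab <- tabulate(sh[keep], nbins = length(gm))
    counts[] <- tab
    counts
}

#' FPKM on masked (non-overlapped) exon length
#'
#' `FPKM(g, s) = counts(g, s) * 1e9 / (masked_length(g) * total(s))`, where
#' `total(s)` is the column sum of counted fragments for sample s and the
#' length is the non-overlapped exonic length from [maskedLengths()]. Genes
#' with masked length 0 are dropped with a warning (FPKM undefined).
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param lengths `data.frame` from [maskedLengths()].
#' @return Numeric FPKM matrix over the genes with positive masked length;
#'   carries `attr(, "unit") == "FPKM"`.
#' @export
computeFpkm <- function(counts, lengths) {
    stopifnot(is.matrix(counts), !is.null(rownames(counts)))
    len <- stats::setNames(lengths$masked_length, lengths$gene_id)
    miss <- setdiff(rownames(counts), names(len))
    if (length(miss))
        stop("no masked length for gene(s): ",
             paste(utils::head(miss, 5L), collapse = ", "))
    len <- len[rownames(counts)]
    if (any(len == 0L)) {
        warning(sum(len == 0L), " gene(s) with masked length 0 dropped ",
                "from FPKM")
        counts <- counts[len > 0L, , drop = FALSE]
        len <- len[len > 0L]
    }
    totals <- colSums(counts)
    if (any(totals == 0))
        stop("zero fragment total in sample(s): ",
             paste(colnames(counts)[totals == 0], collapse = ", "))
    fpkm <- counts * 1e9 / outer(as.numeric(len), as.numeric(totals))
    attr(fpkm, "unit") <- "FPKM"
    fpkm
}

#' Prevalence filter for expressed genes
#'
#' Keeps a gene when its FPKM is at or above `minValue` in at least
#' `ceiling(minFraction * n_samples)` samples (both thresholds inclusive).
#' This defines the "expressed" gene set entering all downstream analyses.
#'
#' @param fpkm Numeric FPKM matrix (genes x samples).
#' @param minValue Expression threshold (FPKM), default 1.
#' @param minFraction Minimum fraction of samples, default 0.10.
#' @return Character vector of kept gene ids, in input order.
#' @export
filterLowExpression <- function(fpkm, minValue = 1, minFraction = 0.10) {
    if (length(fpkm) == 0L || nrow(fpkm) == 0L) return(character())
    need <- ceiling(minFraction * ncol(fpkm))
    keep <- rowSums(fpkm >= minValue) >= need
    rownames(fpkm)[keep]
}

#' Read fragments from a BED file
#'
#' Convenience reader for the toy counter: the first three BED columns
#' define the fragment intervals.
#'
#' @param path BED file path.
#' @return A `GRanges` of fragments.
#' @export
readFragmentsBed <- function(path) {
    rtracklayer::import(path, format = "BED")
}
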