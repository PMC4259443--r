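#' @include AllClasses.R
NULL

#' lncRNA-mRNA Pearson correlation matrix
#'
#' Pearson correlation across samples for every (lncRNA, mRNA) pair.
#' Constant rows carry no correlation signal and are dropped with a
#' warning.
#'
#' @param lncExpr,mrnaExpr Numeric matrices, genes x samples, with the same
#'   samples in the same order (at least 3).
#' @return Numeric matrix `r` (lncRNA x mRNA) in \[-1, 1\].
#' @export
correlationMatrix <- function(lncExpr, mrnaExpr) {
    if (ncol(lncExpr) != ncol(mrnaExpr) ||
        (!is.null(colnames(lncExpr)) &&
         !identical(colnames(lncExpr), colnames(mrnaExpr))))
        stop("expression matrices must share the same samples in order")
    if (ncol(lncExpr) < 3L) stop("need at least 3 shared samples")
    dropConst <- function(m, what) {
        sds <- apply(m, 1L, stats::sd)
        if (any(sds == 0)) {
            warning("dropping ", sum(sds == 0), " constant ", what,
                    " row(s)")
            m <- m[sds > 0, , drop = FALSE]
        }
        m
    }
    lncExpr <- dropConst(lncExpr, "lncRNA")
    mrnaExpr <- dropConst(mrnaExpr, "mRNA")
    stats::cor(t(lncExpr), t(mrnaExpr))
}

#' Ternarize a correlation matrix at the distribution tails
#'
#' Assigns +1 to the `floor(tail * N)` largest entries of the whole matrix,
#' -1 to the `floor(tail * N)` smallest, and 0 elsewhere (`N` = total
#' entries, global quantiles). Ties at either cutoff are broken by
#' ascending (row index, column index); positives are assigned first, and
#' a cell already positive is never also made negative (relevant only for
#' degenerate all-equal inputs, which are flagged).
#'
#' @param r Numeric matrix with finite entries.
#' @param tail Tail fraction per sign (default 0.01).
#' @return A [TernaryMatrix-class].
#' @export
ternarize <- function(r, tail = 0.01) {
    stopifnot(all(is.finite(r)))
    N <- length(r)
    m <- floor(tail * N)
    e <- matrix(0L, nrow(r), ncol(r), dimnames = dimnames(r))
    if (m < 1) {
        message("tail * N < 1; ternary matrix is all zeros")
        return(new("TernaryMatrix", entries = e, tail = tail))
    }
    ri <- as.vector(row(r)); ci <- as.vector(col(r)); v <- as.vector(r)
    up <- order(-v, ri, ci)[seq_len(m)]
    e[up] <- 1L
    lo <- order(v, ri, ci)
    lo <- lo[!(lo %in% up)][seq_len(min(m, N - m))]
    e[lo] <- -1L
    if (stats::sd(v) == 0)
        message("degenerate input: all entries equal; ternary assignment ",
                "is tie-broken by index")
    new("TernaryMatrix", entries = e, tail = tail)
}

#' Two-way clustering of a ternary matrix
#'
#' Independent hierarchical clustering of the rows and of the columns
#' (Euclidean distance, complete linkage); returns the leaf orders used to
#' lay the matrix out as a heatmap.
#'
#' @param tm A [TernaryMatrix-class].
#' @return List with `rowOrder`, `colOrder` (integer permutations) and the
#'   `hclust` trees (`NULL` for single rows/columns).
#' @export
clusterTernary <- function(tm) {
    e <- ternaryEntries(tm)
    oneWay <- function(m) {
        if (nrow(m) < 2L)
            return(list(order = seq_len(nrow(m)), tree = NULL))
        h <- stats::hclust(stats::dist(m), method = "complete")
        list(order = h$order, tree = h)
    }
    ro <- oneWay(e)
    co <- oneWay(t(e))
    list(rowOrder = ro$order, colOrder = co$order,
         rowTree = ro$tree, colTree = co$tree)
}

#' Correlations of lncRNAs with their genomic neighbor genes
#'
#' Looks up the Pearson correlation of every assigned (lncRNA, coding
#' neighbor) pair in the correlation matrix and reports them sorted by
#' absolute correlation, the read-out for cis-acting candidates. Pairs
#' absent from the matrix are skipped with a message.
#'
#' @param neighbors `data.frame` from [assignNeighbors()].
#' @param r Correlation matrix from [correlationMatrix()] (lncRNA rows,
#'   mRNA columns).
#' @return `data.frame` with `lnc_gene_id`, `coding_gene_id`, `distance`,
#'   `rule`, `r`, sorted by `|r|` descending.
#' @export
cisReport <- function(neighbors, r) {
    if (nrow(neighbors) == 0L)
        return(data.frame(lnc_gene_id = character(),
                          coding_gene_id = character(),
                          distance = integer(), rule = character(),
                          r = numeric(), stringsAsFactors = FALSE))
    ok <- neighbors$lnc_gene_id %in% rownames(r) &
        neighbors$coding_gene_id %in% colnames(r)
    if (any(!ok))
        message(sum(!ok), " neighbor pair(s) missing from the expression ",
                "matrices; skipped")
    nb <- neighbors[ok, , drop = FALSE]
    nb$r <- r[cbind(nb$lnc_gene_id, nb$coding_gene_id)]
    nb <- nb[order(-abs(nb$r)), , drop = FALSE]
    rownames(nb) <- NULL
    nb
}
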