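#' @include AllClasses.R
NULL

#' Rank mRNAs by correlation with a lncRNA phenotype
#'
#' Uses the lncRNA's expression profile as a continuous phenotype: every
#' mRNA is scored by its Pearson correlation with the profile and the list
#' is sorted by descending correlation (ties broken by gene id ascending).
#'
#' @param lncId lncRNA identifier (a row of `lncExpr`).
#' @param lncExpr,mrnaExpr Expression matrices sharing samples in order.
#' @return List with `phenotype`, `genes` (sorted ids) and `scores` (the
#'   correlations, non-increasing).
#' @export
rankByPhenotype <- function(lncId, lncExpr, mrnaExpr) {
    if (ncol(mrnaExpr) < 3L) stop("need at least 3 shared samples")
    x <- lncExpr[lncId, ]
    if (stats::sd(x) == 0)
        stop("constant lncRNA profile: ", lncId)
    r <- as.vector(stats::cor(x, t(mrnaExpr)))
    names(r) <- rownames(mrnaExpr)
    ord <- order(-r, names(r))
    list(phenotype = lncId, genes = names(r)[ord],
         scores = unname(r[ord]))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating `|score|^p / N_R` at genes in the set
#' (`N_R` = sum of in-set weights) and `-1 / (N - N_H)` at genes outside
#' it; the enrichment score is the running-sum value of largest magnitude,
#' sign retained. With `p = 0` all hits weigh equally (the classical KS
#' statistic).
#'
#' @param ranked A ranked list from [rankByPhenotype()].
#' @param geneSet Character vector of gene ids.
#' @param p Weighting exponent (default 1).
#' @return List with `es` and the full `running` sum; `NULL` (with a
#'   message) when the set does not intersect the ranked genes.
#' @export
enrichmentScore <- function(ranked, geneSet, p = 1) {
    hits <- ranked$genes %in% geneSet
    if (!any(hits)) {
        message("gene set does not intersect the ranked list; untestable")
        return(NULL)
    }
    es <- esFromHits(ranked$scores, hits, p)
    list(es = es$es, running = es$running)
}

## core running-sum computation on a logical hit vector
esFromHits <- function(scores, hits, p) {
    N <- length(hits)
    NH <- sum(hits)
    w <- abs(scores)^p
    NR <- sum(w[hits])
    if (NR == 0) { w <- rep(1, N); NR <- NH }   # degenerate all-zero scores
    step <- ifelse(hits, w / NR,
                   if (N > NH) -1 / (N - NH) else 0)
    running <- cumsum(step)
    list(es = running[which.max(abs(running))], running = running)
}

#' Per-lncRNA gene-set enrichment screen with permutation NES and FDR
#'
#' For every lncRNA phenotype and gene set: the observed enrichment score
#' on the correlation-ranked mRNA list, a null distribution of scores from
#' `nPerm` random gene-label permutations (random sets of the same size on
#' the same ranked list; nulls are shared across sets of equal size within
#' a phenotype), the normalized score `NES = es / mean(|null| of matching
#' sign)`, a sign-specific permutation p-value, BH adjustment across all
#' (lncRNA, set) pairs, and the ternary call: `sign(NES)` when
#' `fdr < fdrMax`, else 0.
#'
#' @param lncExpr,mrnaExpr Expression matrices sharing samples in order.
#' @param geneSets Named list of gene-id vectors (e.g. from [readGmt()]).
#' @param p Weighting exponent (default 1).
#' @param nPerm Number of permutations (default 1000; must be >= 1).
#' @param seed RNG seed (caller's RNG state is preserved).
#' @param fdrMax FDR threshold for the ternary call (default 0.05).
#' @param lncIds Phenotypes to screen (default: all rows of `lncExpr`).
#' @return `data.frame` with `lnc_id`, `set_id`, `es`, `nes`, `p_value`,
#'   `fdr`, `ternary`. Pairs with an empty intersection or no
#'   matching-sign nulls are flagged `NA` and excluded from BH.
#' @export
gseaScreen <- function(lncExpr, mrnaExpr, geneSets, p = 1, nPerm = 1000,
                       seed = 1, fdrMax = 0.05,
                       lncIds = rownames(lncExpr)) {
    if (nPerm < 1) stop("nPerm must be >= 1")
    old <- globalSeed()
    on.exit(restoreSeed(old), add = TRUE)
    set.seed(seed)
    rows <- list()
    for (lnc in lncIds) {
        ranked <- rankByPhenotype(lnc, lncExpr, mrnaExpr)
        N <- length(ranked$genes)
        sizes <- vapply(geneSets,
                        function(s) sum(ranked$genes %in% s), 1L)
        nulls <- list()   # null ES per distinct set size
        for (nh in unique(sizes[sizes > 0L])) {
            key <- as.character(nh)
            nulls[[key]] <- vapply(seq_len(nPerm), function(i) {
                hit <- logical(N)
                hit[sample.int(N, nh)] <- TRUE
                esFromHits(ranked$scores, hit, p)$es
            }, 1)
        }
        for (si in seq_along(geneSets)) {
            nh <- sizes[si]
            if (nh == 0L) {
                rows[[length(rows) + 1L]] <- data.frame(
                    lnc_id = lnc, set_id = names(geneSets)[si],
                    es = NA_real_, nes = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
                next
            }
            hit <- ranked$genes %in% geneSets[[si]]
            es <- esFromHits(ranked$scores, hit, p)$es
            null <- nulls[[as.character(nh)]]
            same <- null * sign(es) > 0
            if (!any(same)) {
                nes <- NA_real_; pv <- NA_real_
            } else {
                nes <- es / mean(abs(null[same]))
                pv <- (1 + sum(abs(null[same]) >= abs(es))) /
                    (1 + sum(same))
            }
            rows[[length(rows) + 1L]] <- data.frame(
                lnc_id = lnc, set_id = names(geneSets)[si],
                es = es, nes = nes, p_value = pv,
                stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, rows)
    res$fdr <- NA_real_
    ok <- !is.na(res$p_value)
    res$fdr[ok] <- bhAdjust(res$p_value[ok])
    res$ternary <- 0L
    call <- ok & !is.na(res$fdr) & res$fdr < fdrMax
    res$ternary[call] <- as.integer(sign(res$nes[call]))
    res$ternary[!ok] <- NA_integer_
    res
}

#' Ternary NES matrix from a GSEA screen
#'
#' Reshapes the screen result into a lncRNA x gene-set
#' [TernaryMatrix-class] (untestable pairs become 0).
#'
#' @param screen Result of [gseaScreen()].
#' @return A [TernaryMatrix-class].
#' @export
gseaTernaryMatrix <- function(screen) {
    lncs <- unique(screen$lnc_id)
    sets <- unique(screen$set_id)
    e <- matrix(0L, length(lncs), length(sets),
                dimnames = list(lncs, sets))
    t3 <- screen$ternary
    t3[is.na(t3)] <- 0L
    e[cbind(match(screen$lnc_id, lncs), match(screen$set_id, sets))] <- t3
    new("TernaryMatrix", entries = e, tail = NA_real_)
}

#' Bicluster a ternary NES matrix
#'
#' Two-way hierarchical clustering (Euclidean, complete) plus a scan for
#' maximal constant-sign blocks: row and column trees are cut at every
#' number of groups up to `maxCuts`, and each (row-group x column-group)
#' cell whose entries all share one nonzero sign and whose dimensions reach
#' `minRows` x `minCols` is reported; blocks contained in a larger
#' same-sign block are dropped.
#'
#' @param tm A [TernaryMatrix-class].
#' @param minRows,minCols Minimum block size (defaults 3 and 2).
#' @param maxCuts Maximum tree-cut granularity (default 10).
#' @return List with `rowOrder`, `colOrder` and `blocks` (each a list with
#'   `rows`, `cols`, `sign`).
#' @export
biclusterTernary <- function(tm, minRows = 3, minCols = 2, maxCuts = 10) {
    e <- ternaryEntries(tm)
    ord <- clusterTernary(tm)
    blocks <- list()
    if (any(e != 0L) && !is.null(ord$rowTree) && !is.null(ord$colTree)) {
        for (kr in seq_len(min(maxCuts, nrow(e)))) {
            rg <- if (kr == 1L) rep(1L, nrow(e)) else
                stats::cutree(ord$rowTree, kr)
            for (kc in seq_len(min(maxCuts, ncol(e)))) {
                cg <- if (kc == 1L) rep(1L, ncol(e)) else
                    stats::cutree(ord$colTree, kc)
                for (rcl in unique(rg)) for (ccl in unique(cg)) {
                    ri <- which(rg == rcl); ci <- which(cg == ccl)
                    if (length(ri) < minRows || length(ci) < minCols) next
                    sub <- e[ri, ci, drop = FALSE]
                    if (all(sub == 1L) || all(sub == -1L))
                        blocks[[length(blocks) + 1L]] <- list(
                            rows = rownames(e)[ri],
                            cols = colnames(e)[ci],
                            sign = sub[1L])
                }
            }
        }
        blocks <- dropContainedBlocks(blocks)
    }
    list(rowOrder = ord$rowOrder, colOrder = ord$colOrder, blocks = blocks)
}

dropContainedBlocks <- function(blocks) {
    if (length(blocks) < 2L) return(blocks)
    keep <- rep(TRUE, length(blocks))
    for (i in seq_along(blocks)) for (j in seq_along(blocks)) {
        if (i == j || !keep[i]) next
        bi <- blocks[[i]]; bj <- blocks[[j]]
        if (bi$sign == bj$sign &&
            all(bi$rows %in% bj$rows) && all(bi$cols %in% bj$cols) &&
            (length(bi$rows) < length(bj$rows) ||
             length(bi$cols) < length(bj$cols)))
            keep[i] <- FALSE
    }
    blocks[keep]
}

#' Hypergeometric enrichment of neighbor genes in gene sets
#'
#' One-sided hypergeometric tail test of the overlap between a lncRNA
#' neighborhood gene list and each gene set, against a stated universe,
#' with BH adjustment across sets. Sets disjoint from the universe are
#' skipped.
#'
#' @param neighborGenes Character vector of coding genes assigned as
#'   neighbors.
#' @param geneSets Named list of gene-id vectors.
#' @param universe Character vector containing all assayable genes
#'   (must contain `neighborGenes`).
#' @return `data.frame` with `set_id`, `overlap`, `set_size`, `p_value`,
#'   `fdr`.
#' @export
neighborSetEnrichment <- function(neighborGenes, geneSets, universe) {
    neighborGenes <- unique(neighborGenes)
    if (!all(neighborGenes %in% universe))
        stop("universe must contain all neighbor genes")
    k <- length(neighborGenes)
    N <- length(unique(universe))
    rows <- lapply(names(geneSets), function(id) {
        s <- intersect(geneSets[[id]], universe)
        if (!length(s)) return(NULL)
        x <- length(intersect(neighborGenes, s))
        m <- length(s)
        data.frame(set_id = id, overlap = x, set_size = m,
                   p_value = stats::phyper(x - 1, m, N - m, k,
                                           lower.tail = FALSE),
                   stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (!length(rows))
        return(data.frame(set_id = character(), overlap = integer(),
                          set_size = integer(), p_value = numeric(),
                          fdr = numeric(), stringsAsFactors = FALSE))
    res <- do.call(rbind, rows)
    res$fdr <- bhAdjust(res$p_value)
    res[order(res$p_value), , drop = FALSE]
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return Named list of gene-id vectors.
#' @export
readGmt <- function(path) {
    fgsea::gmtPathways(path)
}
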