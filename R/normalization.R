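#' @include AllClasses.R
NULL

#' Median-of-ratios size factors
#'
#' The size factor of a sample is the median, over genes with a positive
#' geometric mean, of the ratio of that sample's count to the gene's
#' geometric mean across samples. This brings library depths to a common
#' scale without being driven by a handful of highly expressed genes.
#'
#' @param counts Integer matrix, genes x samples.
#' @return Named numeric vector of positive size factors.
#' @export
estimateSizeFactors <- function(counts) {
    logGeo <- rowMeans(log(counts))
    use <- is.finite(logGeo)
    if (!any(use))
        stop("no gene with a positive geometric mean; cannot estimate ",
             "size factors")
    geo <- exp(logGeo[use])
    sf <- apply(counts, 2L, function(x) stats::median(x[use] / geo))
    if (any(!is.finite(sf) | sf <= 0))
        stop("non-positive size factor estimated")
    sf
}

#' Normalize a count matrix by size factors
#'
#' Divides each column by its size factor.
#'
#' @param counts Integer matrix, genes x samples.
#' @param sf Named size factors covering every column.
#' @return Numeric matrix of normalized counts, `attr(, "unit") ==
#'   "normalized_counts"`.
#' @export
normalizeCounts <- function(counts, sf) {
    if (!is.null(colnames(counts))) {
        miss <- setdiff(colnames(counts), names(sf))
        if (length(miss))
            stop("missing size factor for sample(s): ",
                 paste(miss, collapse = ", "))
        sf <- sf[colnames(counts)]
    } else if (length(sf) != ncol(counts)) {
        stop("size factors do not match the number of samples")
    }
    z <- sweep(counts, 2L, sf, "/")
    attr(z, "unit") <- "normalized_counts"
    z
}

#' Method-of-moments dispersions with a parametric trend
#'
#' Per-gene negative-binomial dispersions are estimated by the method of
#' moments on normalized counts pooled within groups: the within-group
#' variance in excess of the shot-noise term `mu * mean(1/sf)` is divided
#' by `mu^2`. A single-parameter trend `nu(mu) = mu + alpha * mu^2` is then
#' fitted across genes by least squares of the excess variance on `mu^2`,
#' and the working dispersion of each gene is the larger of its own
#' estimate and the trend, floored at `1e-8`. All-zero genes have no
#' defined dispersion and are excluded from testing (p = 1).
#'
#' @param counts Integer matrix, genes x samples.
#' @param sf Size factors.
#' @param groups Factor or vector of group labels, one per sample (at least
#'   2 samples per group).
#' @return List with `geneDisp`, `trendDisp` (scalar alpha), `workingDisp`,
#'   `baseMean`, and `excluded` (all-zero genes).
#' @export
fitDispersions <- function(counts, sf, groups) {
    groups <- as.factor(groups)
    if (any(table(groups) < 2L))
        stop("need at least 2 samples per group")
    z <- normalizeCounts(counts, sf)
    baseMean <- rowMeans(z)
    xi <- mean(1 / sf)
    n <- ncol(z)
    G <- nlevels(groups)
    ss <- matrix(0, nrow(z), 1L)
    pooled <- rep(0, nrow(z))
    for (g in levels(groups)) {
        zg <- z[, groups == g, drop = FALSE]
        mg <- rowMeans(zg)
        pooled <- pooled + rowSums((zg - mg)^2)
    }
    pooledVar <- pooled / (n - G)
    excess <- pooledVar - xi * baseMean
    geneDisp <- ifelse(baseMean > 0, excess / baseMean^2, NA_real_)
    use <- baseMean > 0
    trendDisp <- if (any(use))
        max(0, sum(excess[use] * baseMean[use]^2) / sum(baseMean[use]^4))
    else 0
    working <- pmax(geneDisp, trendDisp, 1e-8)
    working[!use] <- NA_real_
    list(geneDisp = geneDisp, trendDisp = trendDisp,
         workingDisp = working, baseMean = baseMean,
         excluded = rownames(counts)[!use])
}

## conditional NB exact test for one gene given group count sums and
## per-group size-factor sums; vectorized over the K+1 outcomes
nbExactPValue <- function(kA, kB, sfA, sfB, alpha) {
    K <- kA + kB
    if (K == 0) return(1)
    SA <- sum(sfA); SB <- sum(sfB)
    q <- K / (SA + SB)
    muA <- q * SA; muB <- q * SB
    ## group sums of per-sample NB(mu = q*sf, alpha): variance
    ## q*S + alpha*q^2*sum(sf^2)  =>  size = S^2 / (alpha * sum(sf^2))
    sizeA <- SA^2 / (alpha * sum(sfA^2))
    sizeB <- SB^2 / (alpha * sum(sfB^2))
    a <- 0:K
    lp <- stats::dnbinom(a, mu = muA, size = sizeA, log = TRUE) +
        stats::dnbinom(K - a, mu = muB, size = sizeB, log = TRUE)
    lp <- lp - max(lp)
    p <- exp(lp)
    pObs <- p[kA + 1L]
    sum(p[p <= pObs * (1 + 1e-7)]) / sum(p)
}

#' Negative-binomial conditional exact test
#'
#' For each gene, conditions on the total count `K = K_A + K_B` over the two
#' groups and sums, over all splits `a + (K - a) = K`, the probabilities no
#' larger than that of the observed split, under independent NB models for
#' the group sums with means proportional to the group size-factor sums and
#' variance from the working dispersion. Probabilities are normalized over
#' the `K + 1` outcomes. Genes with `K = 0` (and all-zero genes excluded
#' from dispersion fitting) get p = 1.
#'
#' @param counts Integer matrix, genes x samples.
#' @param sf Size factors.
#' @param groups Two-level factor over samples.
#' @param dispersions Result of [fitDispersions()]; fitted on demand when
#'   omitted.
#' @return Named numeric vector of p-values in \[0, 1\].
#' @export
nbExactTest <- function(counts, sf, groups, dispersions = NULL) {
    groups <- as.factor(groups)
    if (nlevels(groups) != 2L)
        stop("nbExactTest requires exactly two groups")
    if (is.null(dispersions))
        dispersions <- fitDispersions(counts, sf, groups)
    iA <- groups == levels(groups)[1L]
    sfA <- sf[iA]; sfB <- sf[!iA]
    p <- rep(1, nrow(counts))
    names(p) <- rownames(counts)
    for (i in seq_len(nrow(counts))) {
        alpha <- dispersions$workingDisp[i]
        if (is.na(alpha)) next
        p[i] <- nbExactPValue(sum(counts[i, iA]), sum(counts[i, !iA]),
                              sfA, sfB, alpha)
    }
    pmin(p, 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (with the usual monotonicity
#' enforcement), preserving input order. Thin wrapper over
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of BH-adjusted values.
#' @export
bhAdjust <- function(p) {
    stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
    stats::p.adjust(p, method = "BH")
}

#' One-vs-rest subtype marker genes
#'
#' Tests every gene for overexpression in the target cluster against all
#' other samples pooled, using the NB exact test with dispersions fitted on
#' the two pooled groups, and BH adjustment across all tested genes. The
#' fold change is computed on normalized means with a pseudocount:
#' `(mean_target + pc) / (mean_rest + pc)`. Markers are the genes passing
#' `fold_change >= fcMin` and `fdr < fdrMax`, sorted by fdr then descending
#' fold change.
#'
#' @param counts Integer matrix, genes x samples.
#' @param sf Size factors.
#' @param clusterLabels Cluster assignment per sample (>= 2 clusters).
#' @param targetCluster The cluster whose markers are sought.
#' @param fcMin Minimum fold change (default 2).
#' @param fdrMax FDR threshold (default 0.05).
#' @param pseudocount Stabilizer for zero means (default 1).
#' @param all When `TRUE`, return the full per-gene table instead of only
#'   the passing markers.
#' @return `data.frame` with `gene_id`, `mean_norm_target`,
#'   `mean_norm_rest`, `fold_change`, `p_value`, `fdr`.
#' @export
subtypeMarkers <- function(counts, sf, clusterLabels, targetCluster,
                           fcMin = 2, fdrMax = 0.05, pseudocount = 1,
                           all = FALSE) {
    clusterLabels <- as.character(clusterLabels)
    if (length(unique(clusterLabels)) < 2L)
        stop("need at least 2 clusters")
    inT <- clusterLabels == as.character(targetCluster)
    if (sum(inT) < 2L || sum(!inT) < 2L)
        stop("cluster with fewer than 2 samples")
    grp <- factor(ifelse(inT, "target", "rest"), levels = c("target", "rest"))
    z <- normalizeCounts(counts, sf)
    mT <- rowMeans(z[, inT, drop = FALSE])
    mR <- rowMeans(z[, !inT, drop = FALSE])
    p <- nbExactTest(counts, sf, grp)
    fdr <- bhAdjust(p)
    res <- data.frame(gene_id = rownames(counts),
                      mean_norm_target = mT, mean_norm_rest = mR,
                      fold_change = (mT + pseudocount) / (mR + pseudocount),
                      p_value = p, fdr = fdr,
                      row.names = NULL, stringsAsFactors = FALSE)
    if (all) return(res)
    res <- res[res$fold_change >= fcMin & res$fdr < fdrMax, , drop = FALSE]
    res[order(res$fdr, -res$fold_change), , drop = FALSE]
}

#' Variance-stabilizing transform for NB counts
#'
#' With the fitted mean-variance relation `nu(mu) = mu + alpha * mu^2`, the
#' variance-stabilizing map is the antiderivative of `1 / sqrt(nu(mu))`,
#' here `(2 / sqrt(alpha)) * asinh(sqrt(alpha * mu))`, applied to
#' normalized counts and affine-calibrated so that its value and slope
#' agree with `log2` at the 99th-percentile normalized count. The standard
#' deviation of the transformed values is then roughly constant across the
#' expression range. When `alpha <= 0` the Poisson limit `2 * sqrt(x)`
#' (similarly calibrated) is used.
#'
#' @param counts Integer matrix, genes x samples.
#' @param sf Size factors.
#' @param alpha Trend dispersion; taken from [fitDispersions()] when a
#'   dispersion fit is supplied.
#' @return Numeric matrix on the VST scale, `attr(, "unit") == "VST"`.
#' @export
vstTransform <- function(counts, sf, alpha) {
    if (is.list(alpha)) alpha <- alpha$trendDisp
    z <- normalizeCounts(counts, sf)
    anchor <- stats::quantile(z[z > 0], 0.99, names = FALSE)
    if (!is.finite(anchor) || anchor <= 0) anchor <- 1
    if (alpha <= 1e-12) {
        message("trend dispersion <= 0; using the Poisson-limit ",
                "square-root transform")
        f <- function(x) 2 * sqrt(x)
        fp <- function(x) 1 / sqrt(x)
    } else {
        f <- function(x) 2 / sqrt(alpha) * asinh(sqrt(alpha * x))
        fp <- function(x) 1 / sqrt(x + alpha * x^2)
    }
    A <- (1 / (anchor * log(2))) / fp(anchor)
    B <- log2(anchor) - A * f(anchor)
    v <- A * f(z) + B
    attr(v, "unit") <- "VST"
    v
}
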