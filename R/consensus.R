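#' @include AllClasses.R
NULL

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the columns (samples) of an expression
#' matrix, cut into exactly `k` clusters. The Pearson distance is `1 - r`
#' over the feature vectors; Ward linkage uses the classical update on
#' squared dissimilarities (`stats::hclust(method = "ward.D2")`).
#'
#' @param mat Numeric matrix, features x samples.
#' @param distance `"pearson"` (1 - correlation) or `"euclidean"`.
#' @param linkage `"ward"` or `"complete"`.
#' @param k Number of clusters (`2 <= k <= n`).
#' @return Named integer vector of cluster labels per sample.
#' @export
hierCluster <- function(mat, distance = c("pearson", "euclidean"),
                        linkage = c("ward", "complete"), k) {
    distance <- match.arg(distance)
    linkage <- match.arg(linkage)
    n <- ncol(mat)
    stopifnot(k >= 1, k <= n)
    if (distance == "pearson") {
        sds <- apply(mat, 2L, stats::sd)
        if (any(sds == 0))
            stop("constant sample profile under pearson distance: ",
                 paste(utils::head(colnames(mat)[sds == 0], 5L),
                       collapse = ", "))
        d <- stats::as.dist(1 - stats::cor(mat))
    } else {
        d <- stats::dist(t(mat))
    }
    h <- stats::hclust(d, method = if (linkage == "ward") "ward.D2"
                                   else "complete")
    stats::cutree(h, k = k)
}

#' Resampled consensus clustering
#'
#' Runs `nRuns` perturbed clusterings: in each run a random 80% of the
#' samples and 80% of the features are drawn without replacement, the
#' subsample is clustered by [hierCluster()] (Pearson distance, Ward
#' linkage) into `k` clusters, and co-cluster indicators are accumulated.
#' The consensus for a pair is the number of runs the pair co-clustered
#' divided by the number of runs it was co-sampled, so rarely drawn pairs
#' are not biased low; pairs never co-sampled get consensus 0 with a
#' message. The run RNG is seeded `seed + run`, making results bit-exactly
#' reproducible; the caller's RNG state is untouched.
#'
#' @param mat Numeric matrix, features x samples (variance-stabilized
#'   expression).
#' @param k Number of clusters inside each run.
#' @param nRuns Number of resampling runs (default 500).
#' @param fracSamples,fracFeatures Subsampling fractions (default 0.8;
#'   subset sizes are `floor(frac * n)`).
#' @param seed Base RNG seed.
#' @return A [ConsensusMatrix-class].
#' @export
runConsensus <- function(mat, k, nRuns = 500, fracSamples = 0.8,
                         fracFeatures = 0.8, seed = 1) {
    if (nRuns < 1) stop("nRuns must be >= 1")
    n <- ncol(mat)
    ids <- colnames(mat)
    if (is.null(ids)) ids <- as.character(seq_len(n))
    ns <- floor(fracSamples * n)
    nf <- floor(fracFeatures * nrow(mat))
    stopifnot(ns >= k, nf >= 1)
    old <- globalSeed()
    on.exit(restoreSeed(old), add = TRUE)
    conn <- matrix(0, n, n)
    cos <- matrix(0L, n, n)
    for (r in seq_len(nRuns)) {
        set.seed(seed + r)
        si <- sort(sample.int(n, ns))
        fi <- sort(sample.int(nrow(mat), nf))
        lab <- hierCluster(mat[fi, si, drop = FALSE], "pearson", "ward", k)
        same <- outer(lab, lab, "==")
        conn[si, si] <- conn[si, si] + same
        cos[si, si] <- cos[si, si] + 1L
    }
    M <- ifelse(cos > 0L, conn / pmax(cos, 1L), 0)
    never <- sum(cos[upper.tri(cos)] == 0L)
    if (never > 0)
        message(never, " sample pair(s) never co-sampled; consensus set ",
                "to 0 for them")
    diag(M) <- 1
    dimnames(M) <- list(ids, ids)
    dimnames(cos) <- list(ids, ids)
    new("ConsensusMatrix", M = M, coSampled = cos,
        nRuns = as.integer(nRuns), k = as.integer(k))
}

#' Cluster the consensus matrix
#'
#' Treats each row of the consensus matrix as the sample's feature vector
#' and applies hierarchical clustering with Euclidean distance and Ward
#' linkage, cut into `k` clusters. This yields the final subtype
#' assignment.
#'
#' @param cm A [ConsensusMatrix-class].
#' @param k Number of clusters.
#' @return Named integer vector of cluster labels.
#' @export
clusterConsensus <- function(cm, k) {
    M <- consensusValues(cm)
    ## M is symmetric: columns are the row profiles
    hierCluster(M, "euclidean", "ward", k)
}

#' Choose the number of clusters by BIC
#'
#' For each candidate `k`, runs the full consensus pipeline
#' ([runConsensus()] then [clusterConsensus()]) and scores the hard
#' partition under a spherical Gaussian mixture: the samples are points in
#' a feature space, the within-cluster sum of squares gives a common
#' variance, and `BIC = -2 logLik + (k * d + 1) * log(n)`. By default the
#' feature space is the expression matrix itself (`space = "expression"`),
#' which is the same space for every `k` and so makes the BIC values
#' comparable; `space = "consensus"` instead uses the rows of each k's own
#' consensus matrix. Degenerate (singleton) clusters are scored with the
#' pooled variance and flagged.
#'
#' @param mat Numeric matrix, features x samples.
#' @param kRange Candidate cluster numbers (default `2:8`).
#' @param nRuns,fracSamples,fracFeatures,seed Passed to [runConsensus()].
#' @param space Feature space for the BIC computation; see Details.
#' @return List with `kStar` (the BIC-minimizing k), `table`
#'   (`data.frame` of k, BIC, flagged) and `labels` (list of partitions
#'   per k).
#' @export
selectK <- function(mat, kRange = 2:8, nRuns = 100, fracSamples = 0.8,
                    fracFeatures = 0.8, seed = 1,
                    space = c("expression", "consensus")) {
    space <- match.arg(space)
    stopifnot(all(kRange >= 1), all(kRange <= ncol(mat)))
    bic <- numeric(length(kRange))
    flagged <- logical(length(kRange))
    labels <- vector("list", length(kRange))
    for (i in seq_along(kRange)) {
        k <- kRange[i]
        cm <- runConsensus(mat, k, nRuns = nRuns,
                           fracSamples = fracSamples,
                           fracFeatures = fracFeatures, seed = seed)
        lab <- clusterConsensus(cm, k)
        X <- if (space == "expression") t(mat) else consensusValues(cm)
        sc <- sphericalBic(X, lab, k)
        bic[i] <- sc$bic
        flagged[i] <- sc$flagged
        labels[[i]] <- lab
    }
    names(labels) <- as.character(kRange)
    list(kStar = kRange[which.min(bic)],
         table = data.frame(k = kRange, bic = bic, flagged = flagged),
         labels = labels)
}

## BIC of a hard spherical-Gaussian partition of the rows of X
sphericalBic <- function(X, labels, k) {
    n <- nrow(X); d <- ncol(X)
    rss <- 0
    sizes <- table(labels)
    for (cl in names(sizes)) {
        Xi <- X[labels == cl, , drop = FALSE]
        mu <- colMeans(Xi)
        rss <- rss + sum(sweep(Xi, 2L, mu)^2)
    }
    sigma2 <- max(rss / (n * d), .Machine$double.eps)
    ll <- -0.5 * n * d * (log(2 * pi * sigma2) + 1)
    list(bic = -2 * ll + (k * d + 1) * log(n),
         flagged = any(sizes < 2L))
}

## save / restore the caller's RNG state so that internally seeded
## procedures do not disturb the session stream
globalSeed <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}

restoreSeed <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else {
        assign(".Random.seed", old, envir = globalenv())
    }
}
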