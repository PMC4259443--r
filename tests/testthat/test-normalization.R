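test_that("size factors solve the scaled-sample fixture analytically", {
    counts <- matrix(c(10L, 40L, 100L, 20L, 80L, 200L), 3, 2,
                     dimnames = list(paste0("g", 1:3), c("a", "b")))
    sf <- estimateSizeFactors(counts)
    ## sample b = 2 x sample a forces factors (1/sqrt(2), sqrt(2))
    expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
    same <- cbind(counts[, 1], counts[, 1])
    expect_equal(unname(estimateSizeFactors(same)), c(1, 1))
    expect_error(estimateSizeFactors(matrix(c(0L, 1L, 1L, 0L), 2, 2)),
                 "geometric mean")
})

test_that("size factors equal a scalar sorted-median loop and DESeq2", {
    set.seed(8)
    counts <- matrix(rnbinom(200, mu = 50, size = 5), 20, 10,
                     dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
    sf <- estimateSizeFactors(counts)
    for (j in 1:10) {
        ratios <- numeric()
        for (i in 1:20) {
            geo <- exp(mean(log(counts[i, ])))
            if (is.finite(geo) && geo > 0)
                ratios <- c(ratios, counts[i, j] / geo)
        }
        s <- sort(ratios)
        m <- length(s)
        med <- if (m %% 2 == 1) s[(m + 1) / 2]
               else (s[m / 2] + s[m / 2 + 1]) / 2
        expect_equal(unname(sf[j]), med, tolerance = 1e-12)
    }
    ## with an odd gene count per median the ratio-scale median equals
    ## DESeq2's log-scale convention exactly
    expect_equal(unname(estimateSizeFactors(counts[1:19, ])),
                 unname(DESeq2::estimateSizeFactorsForMatrix(
                     counts[1:19, ])),
                 tolerance = 1e-10)
    ## gene-order invariance
    expect_equal(estimateSizeFactors(counts[sample(20), ]), sf)
})

test_that("normalization divides columns and undoes pure depth scaling", {
    counts <- matrix(c(10L, 40L, 100L, 20L, 80L, 200L), 3, 2,
                     dimnames = list(paste0("g", 1:3), c("a", "b")))
    z <- normalizeCounts(counts, estimateSizeFactors(counts))
    expect_equal(z[, "a"], z[, "b"])
    ident <- normalizeCounts(counts, setNames(c(1, 1), c("a", "b")))
    expect_equal(unname(ident[, "a"]), as.numeric(counts[, "a"]))
    expect_error(normalizeCounts(counts, setNames(1, "a")), "missing")
    set.seed(3)
    cts <- matrix(rpois(40, 30), 8, 5,
                  dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
    sf <- estimateSizeFactors(cts)
    z2 <- normalizeCounts(cts, sf)
    for (i in 1:8) for (j in 1:5)
        expect_equal(z2[i, j], unname(cts[i, j] / sf[j]))
})

test_that("dispersion fitting recovers the Poisson limit and an NB truth", {
    set.seed(77)
    n <- 100
    sf <- setNames(rep(1, n), paste0("s", 1:n))
    grp <- rep(c("A", "B"), each = n / 2)
    ## Poisson data: fitted trend is essentially zero
    mu <- runif(200, 20, 200)
    pois <- t(vapply(mu, function(m) rpois(n, m), numeric(n)))
    dimnames(pois) <- list(paste0("g", 1:200), names(sf))
    dPois <- fitDispersions(pois, sf, grp)
    expect_lte(dPois$trendDisp, 0.01)
    ## NB at alpha = 0.2: trend lands in [0.1, 0.4]
    nb <- t(vapply(mu, function(m) rnbinom(n, mu = m, size = 5),
                   numeric(n)))
    dimnames(nb) <- dimnames(pois)
    dNB <- fitDispersions(nb, sf, grp)
    expect_gte(dNB$trendDisp, 0.1)
    expect_lte(dNB$trendDisp, 0.4)
    ## constant gene: negative moment estimate is floored
    const <- matrix(5L, 1, n, dimnames = list("flat", names(sf)))
    dC <- fitDispersions(rbind(const, pois[1:5, ]), sf, grp)
    expect_lte(dC$geneDisp["flat"], 0)
    expect_gte(dC$workingDisp["flat"], 1e-8)
    ## all-zero genes are excluded
    zero <- matrix(0L, 1, n, dimnames = list("zero", names(sf)))
    dZ <- fitDispersions(rbind(zero, pois[1:5, ]), sf, grp)
    expect_identical(dZ$excluded, "zero")
})

test_that("the NB exact test matches full enumeration and is symmetric", {
    set.seed(12)
    for (rep in 1:30) {
        nA <- sample(2:5, 1); nB <- sample(2:5, 1)
        sfA <- runif(nA, 0.5, 2); sfB <- runif(nB, 0.5, 2)
        kA <- sample(0:30, 1); kB <- sample(0:20, 1)
        alpha <- runif(1, 0.05, 0.5)
        expect_equal(
            lncScape:::nbExactPValue(kA, kB, sfA, sfB, alpha),
            nbEnumOracle(kA, kB, sfA, sfB, alpha),
            tolerance = 1e-12)
        ## group swap leaves the p-value unchanged
        expect_equal(
            lncScape:::nbExactPValue(kA, kB, sfA, sfB, alpha),
            lncScape:::nbExactPValue(kB, kA, sfB, sfA, alpha),
            tolerance = 1e-12)
    }
    ## perfectly balanced counts in a symmetric design sit at the mode
    expect_equal(lncScape:::nbExactPValue(25, 25, rep(1, 4), rep(1, 4),
                                          0.1), 1)
    expect_equal(lncScape:::nbExactPValue(0, 0, rep(1, 3), rep(1, 3),
                                          0.1), 1)
})

test_that("BH adjustment reproduces the hand-worked step-up values", {
    ## q_i = min_j>=i (m * p_j / j): all four collapse to 0.04 here
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.37), 0.37)
    expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
    ## permutation invariance after un-permuting
    set.seed(4)
    p <- runif(20)
    perm <- sample(20)
    expect_equal(bhAdjust(p[perm])[order(perm)], bhAdjust(p))
    ## fdr never drops below p on monotone inputs
    expect_true(all(bhAdjust(p) >= p))
})

test_that("subtype markers recover planted fold changes without false calls", {
    set.seed(60)
    n <- 40
    grp <- rep(1:2, each = n / 2)
    mu <- runif(120, 30, 300)
    counts <- t(vapply(mu, function(m) rnbinom(n, mu = m, size = 10),
                       numeric(n)))
    ## first 20 genes up 4-fold in cluster 1
    for (i in 1:20)
        counts[i, grp == 1] <- rnbinom(n / 2, mu = 4 * mu[i], size = 10)
    dimnames(counts) <- list(paste0("g", 1:120), paste0("s", 1:n))
    sf <- estimateSizeFactors(counts)
    mk <- subtypeMarkers(counts, sf, grp, 1)
    expect_gte(sum(paste0("g", 1:20) %in% mk$gene_id), 18)
    expect_equal(sum(!(mk$gene_id %in% paste0("g", 1:20))), 0)
    ## identical groups yield no markers; an infinite threshold too
    expect_equal(nrow(subtypeMarkers(counts[21:120, ], sf, grp, 1)), 0)
    expect_equal(nrow(subtypeMarkers(counts, sf, grp, 1, fcMin = Inf)), 0)
    expect_error(subtypeMarkers(counts, sf, c(1, rep(2, n - 1)), 1),
                 "fewer than 2")
})

test_that("the VST flattens NB variance and falls back to sqrt for Poisson", {
    set.seed(30)
    n <- 60
    sf <- setNames(rep(1, n), paste0("s", 1:n))
    mu <- exp(seq(log(10), log(1e4), length.out = 300))
    counts <- t(vapply(mu, function(m) rnbinom(n, mu = m, size = 10),
                       numeric(n)))
    dimnames(counts) <- list(paste0("g", 1:300), names(sf))
    v <- vstTransform(counts, sf, 0.1)
    sds <- apply(v, 1, sd)
    decile <- cut(mu, quantile(mu, 0:10 / 10), include.lowest = TRUE)
    perDecile <- tapply(sds, decile, median)
    expect_lt(max(perDecile) / min(perDecile), 2)
    ## monotone in the counts
    x <- sort(runif(50, 0, 1e4))
    A <- vstTransform(matrix(as.integer(x), 1, 50,
                             dimnames = list("g", paste0("s", 1:50))),
                      setNames(rep(1, 50), paste0("s", 1:50)), 0.1)
    expect_true(all(diff(as.vector(A)) >= 0))
    ## alpha <= 0: affine image of 2*sqrt(x)
    expect_message(
        v0 <- vstTransform(counts, sf, 0),
        "Poisson")
    z <- normalizeCounts(counts, sf)
    fit <- lm(as.vector(v0) ~ sqrt(as.vector(z)))
    expect_lt(max(abs(residuals(fit))), 1e-8)
})
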