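rankedFixture <- function(nGenes = 50, seed = 1) {
    set.seed(seed)
    scores <- sort(runif(nGenes, -1, 1), decreasing = TRUE)
    list(phenotype = "L1", genes = sprintf("M%03d", seq_len(nGenes)),
         scores = scores)
}

test_that("phenotype ranking orders mRNAs by correlation", {
    set.seed(18)
    n <- 20
    lnc <- matrix(rnorm(n), 1, n, dimnames = list("L1", paste0("s", 1:n)))
    mrna <- rbind(same = lnc[1, ], flip = -lnc[1, ],
                  noise = rnorm(n))
    colnames(mrna) <- colnames(lnc)
    rk <- rankByPhenotype("L1", lnc, mrna)
    expect_equal(rk$genes[1], "same")
    expect_equal(rk$scores[1], 1)
    expect_equal(rk$genes[length(rk$genes)], "flip")
    expect_equal(rk$scores[length(rk$scores)], -1)
    expect_true(all(diff(rk$scores) <= 0))
    lncFlat <- matrix(1, 1, n, dimnames = dimnames(lnc))
    expect_error(rankByPhenotype("L1", lncFlat, mrna), "constant")
    ## random data: order agrees with scalar correlations
    set.seed(19)
    mr <- matrix(rnorm(15 * n), 15, n,
                 dimnames = list(paste0("M", 1:15), colnames(lnc)))
    rk2 <- rankByPhenotype("L1", lnc, mr)
    manual <- vapply(rownames(mr), function(g) cor(lnc[1, ], mr[g, ]), 1)
    expect_equal(rk2$genes, names(sort(-manual)))
})

test_that("enrichment scores match forced cases and the step-wise oracle", {
    rk <- rankedFixture(50)
    ## single member at rank 1 with p = 0: maximal deviation 1
    es1 <- enrichmentScore(rk, rk$genes[1], p = 0)
    expect_equal(es1$es, 1)
    ## set = all genes: no misses, score peaks at the cumulative maximum
    esAll <- enrichmentScore(rk, rk$genes, p = 1)
    w <- abs(rk$scores)
    expect_equal(esAll$es, max(cumsum(w / sum(w))))
    ## empty intersection is untestable
    expect_message(esNone <- enrichmentScore(rk, "ABSENT"), "untestable")
    expect_null(esNone)
    ## random sets against the brute-force running sum
    set.seed(24)
    for (rep in 1:20) {
        set <- sample(rk$genes, 5)
        es <- enrichmentScore(rk, set, p = 1)
        expect_equal(es$es, esOracle(rk$scores, rk$genes %in% set, 1),
                     tolerance = 1e-12)
    }
})

test_that("reversing the ranked list negates the unweighted score", {
    rk <- rankedFixture(40, seed = 3)
    set <- sample(rk$genes, 6)
    fwd <- enrichmentScore(rk, set, p = 0)$es
    rev <- list(phenotype = "L1", genes = rev(rk$genes),
                scores = rev(rk$scores))
    bwd <- enrichmentScore(rev, set, p = 0)$es
    expect_equal(bwd, -fwd, tolerance = 1e-12)
})

test_that("the GSEA screen calls planted sets and stays quiet on null
           sets", {
    set.seed(88)
    n <- 60
    lnc <- matrix(rnorm(2 * n), 2, n,
                  dimnames = list(c("L1", "L2"), paste0("s", 1:n)))
    mrna <- matrix(rnorm(120 * n), 120, n,
                   dimnames = list(sprintf("M%03d", 1:120),
                                   paste0("s", 1:n)))
    for (i in 1:12) mrna[i, ] <- lnc["L1", ] + rnorm(n, sd = 0.4)
    sets <- list(PLANTED = rownames(mrna)[1:12],
                 NULL1 = sample(rownames(mrna)[13:120], 12),
                 NULL2 = sample(rownames(mrna)[13:120], 12))
    scr <- gseaScreen(lnc, mrna, sets, nPerm = 500, seed = 10)
    planted <- scr[scr$lnc_id == "L1" & scr$set_id == "PLANTED", ]
    expect_equal(planted$ternary, 1L)
    expect_gt(planted$nes, 1)
    expect_error(gseaScreen(lnc, mrna, sets, nPerm = 0), "nPerm")
    ## screen output reshapes into a ternary matrix
    tm <- gseaTernaryMatrix(scr)
    expect_equal(dim(ternaryEntries(tm)), c(2L, 3L))
    expect_equal(ternaryEntries(tm)["L1", "PLANTED"], 1L)
})

test_that("biclustering recovers a planted constant-sign block", {
    set.seed(41)
    e <- matrix(0L, 30, 20,
                dimnames = list(paste0("L", 1:30), paste0("S", 1:20)))
    e[sample(length(e), 40)] <- sample(c(1L, -1L), 40, TRUE)
    e[3:12, 2:6] <- 1L
    tm <- new("TernaryMatrix", entries = e, tail = NA_real_)
    bic <- biclusterTernary(tm, minRows = 8, minCols = 4)
    ## a reported all-positive block covers the planted one
    hit <- vapply(bic$blocks, function(b)
        b$sign == 1L &&
        sum(b$rows %in% paste0("L", 3:12)) >= 8 &&
        sum(b$cols %in% paste0("S", 2:6)) >= 4, TRUE)
    expect_true(any(hit))
    ## all-zero matrix has no blocks
    z <- new("TernaryMatrix",
             entries = matrix(0L, 10, 10,
                              dimnames = list(paste0("r", 1:10),
                                              paste0("c", 1:10))),
             tail = NA_real_)
    expect_equal(length(biclusterTernary(z)$blocks), 0L)
    ## transposing the input transposes the blocks
    tmT <- new("TernaryMatrix", entries = t(e), tail = NA_real_)
    bicT <- biclusterTernary(tmT, minRows = 4, minCols = 8)
    hitT <- vapply(bicT$blocks, function(b)
        b$sign == 1L &&
        sum(b$rows %in% paste0("S", 2:6)) >= 4 &&
        sum(b$cols %in% paste0("L", 3:12)) >= 8, TRUE)
    expect_true(any(hitT))
})

test_that("neighbor-set enrichment matches the closed-form
           hypergeometric", {
    universe <- paste0("G", 1:20)
    sets <- list(A = paste0("G", 1:5))
    neigh <- paste0("G", 1:5)
    res <- neighborSetEnrichment(neigh, sets, universe)
    ## all 5 neighbors inside a 5-gene set drawn from 20:
    ## P(X >= 5) = choose(5,5) choose(15,0) / choose(20,5)
    expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
    ## empty neighbor list: p = 1
    resE <- neighborSetEnrichment(character(), sets, universe)
    expect_equal(resE$p_value, 1)
    ## set = universe: p = 1
    resU <- neighborSetEnrichment(neigh, list(U = universe), universe)
    expect_equal(resU$p_value, 1)
    ## disjoint sets are skipped
    resD <- neighborSetEnrichment(neigh, list(D = c("X1", "X2")),
                                  universe)
    expect_equal(nrow(resD), 0L)
})

test_that("GMT files round-trip through the reader", {
    path <- withr::local_tempfile(fileext = ".gmt")
    sets <- list(S1 = c("A", "B", "C"), S2 = c("B", "D"))
    writeGmt(sets, path)
    got <- readGmt(path)
    expect_equal(got[order(names(got))], sets)
})
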