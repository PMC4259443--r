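## Independent oracles and fixture builders shared across the suite.
## Every oracle is deliberately naive (loops, per-base scans, full
## enumeration) and kept apart from the package's own algorithms.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
})

## --- fixtures ---------------------------------------------------------

## small random gene model: exons drawn on a short coordinate range so
## cross-class overlaps are common
randomGeneModel <- function(nCoding = 5, nLnc = 5, maxPos = 2000,
                            chroms = c("c1", "c2")) {
    n <- nCoding + nLnc
    rows <- lapply(seq_len(n), function(i) {
        nEx <- sample(1:3, 1)
        st <- sort(sample.int(maxPos, nEx))
        wid <- sample(50:300, nEx, replace = TRUE)
        data.frame(gene_id = sprintf("g%02d", i),
                   biotype = if (i <= nCoding) "protein_coding"
                             else "lincRNA",
                   chrom = sample(chroms, 1),
                   start = st, end = st + wid,
                   strand = sample(c("+", "-"), 1))
    })
    ex <- do.call(rbind, rows)
    gr <- GRanges(ex$chrom, IRanges(ex$start, ex$end), strand = ex$strand)
    lncScape:::makeGeneModel(ex$gene_id, ex$biotype, ex$gene_id, gr)
}

## well-separated gaussian clusters: features x samples
clusteredMatrix <- function(nPerCluster = c(5, 5), nFeatures = 30,
                            shift = 6, noise = 1) {
    k <- length(nPerCluster)
    centers <- matrix(rnorm(k * nFeatures, sd = shift), nFeatures, k)
    cols <- lapply(seq_len(k), function(j)
        centers[, j] + matrix(rnorm(nFeatures * nPerCluster[j],
                                    sd = noise),
                              nFeatures))
    m <- do.call(cbind, cols)
    colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
    list(mat = m, truth = rep(seq_len(k), nPerCluster))
}

## --- per-base / per-fragment oracles ----------------------------------

## masked length by explicit position sets
bruteMaskedLengths <- function(gm) {
    exl <- exonsByGene(gm)
    lnc <- isLncRNA(gm)
    chromOf <- function(g) as.character(seqnames(g))[1]
    posOf <- function(g) unlist(lapply(seq_along(g), function(j)
        seq(start(g)[j], end(g)[j])))
    vapply(seq_along(exl), function(i) {
        g <- exl[[i]]
        others <- which(lnc != lnc[i])
        opos <- integer()
        for (j in others) {
            o <- exl[[j]]
            if (chromOf(o) != chromOf(g)) next
            opos <- c(opos, posOf(o))
        }
        sum(!(posOf(g) %in% unique(opos)))
    }, 1)
}

## union counting by a per-fragment scan over all genes
bruteUnionCount <- function(fragments, gm) {
    exl <- exonsByGene(gm)
    ids <- geneIds(gm)
    counts <- setNames(integer(length(ids)), ids)
    for (f in seq_along(fragments)) {
        fc <- as.character(seqnames(fragments))[f]
        fs <- start(fragments)[f]; fe <- end(fragments)[f]
        hit <- character()
        for (i in seq_along(exl)) {
            g <- exl[[i]]
            if (as.character(seqnames(g))[1] != fc) next
            if (any(start(g) <= fe & end(g) >= fs))
                hit <- c(hit, ids[i])
        }
        if (length(hit) == 1L) counts[hit] <- counts[hit] + 1L
    }
    counts
}

## basal-plus-extension assignment by explicit per-gene scans
bruteNeighbors <- function(gm, basalUp = 5000, basalDown = 1000,
                           maxExtension = 1e6) {
    g <- gm@genes
    lnc <- isLncRNA(gm)
    cod <- which(!lnc); ln <- which(lnc)
    out <- list()
    for (j in ln) {
        t <- g$tss[j]
        chr <- as.character(seqnames(g))[j]
        for (i in cod) {
            if (as.character(seqnames(g))[i] != chr) next
            minus <- as.character(strand(g))[i] == "-"
            bs <- if (minus) g$tss[i] - basalDown else g$tss[i] - basalUp
            be <- if (minus) g$tss[i] + basalUp else g$tss[i] + basalDown
            others <- setdiff(cod, i)
            others <- others[as.character(seqnames(g))[others] == chr]
            leftEdge <- -Inf; rightEdge <- Inf
            for (o in others) {
                om <- as.character(strand(g))[o] == "-"
                obs <- if (om) g$tss[o] - basalDown else g$tss[o] - basalUp
                obe <- if (om) g$tss[o] + basalUp else g$tss[o] + basalDown
                before <- g$tss[o] < g$tss[i] ||
                    (g$tss[o] == g$tss[i] && g$gene_id[o] < g$gene_id[i])
                if (before) leftEdge <- max(leftEdge, obe + 1)
                else rightEdge <- min(rightEdge, obs - 1)
            }
            ds <- min(bs, max(g$tss[i] - maxExtension, leftEdge))
            de <- max(be, min(g$tss[i] + maxExtension, rightEdge))
            if (t >= ds && t <= de) {
                s <- if (as.character(strand(g))[j] == "-") -1L else 1L
                out[[length(out) + 1L]] <- data.frame(
                    lnc_gene_id = g$gene_id[j],
                    coding_gene_id = g$gene_id[i],
                    distance = s * (g$tss[i] - t),
                    rule = if (t >= bs && t <= be) "basal"
                           else "extension",
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(out))
        return(data.frame(lnc_gene_id = character(),
                          coding_gene_id = character(),
                          distance = integer(), rule = character()))
    res <- do.call(rbind, out)
    res[order(res$lnc_gene_id, res$coding_gene_id), , drop = FALSE]
}

## --- clustering oracle ------------------------------------------------

## naive agglomeration, recomputing all pairwise linkage criteria each
## step; ties broken by the lowest index pair; returns sorted merge
## heights and the partition at every k
naiveAgglom <- function(d, linkage = c("ward", "complete")) {
    linkage <- match.arg(linkage)
    D <- as.matrix(d)
    n <- nrow(D)
    D2 <- D^2
    members <- as.list(seq_len(n))
    active <- seq_len(n)
    cur <- if (linkage == "ward") D2 else D
    heights <- numeric()
    partitions <- list()
    lab <- seq_len(n)
    while (length(active) > 1L) {
        best <- c(NA, NA); bestVal <- Inf
        for (ai in seq_along(active)) for (bi in seq_along(active)) {
            if (bi <= ai) next
            a <- active[ai]; b <- active[bi]
            v <- cur[a, b]
            if (v < bestVal - 1e-12) { bestVal <- v; best <- c(a, b) }
        }
        a <- best[1L]; b <- best[2L]
        heights <- c(heights, if (linkage == "ward") sqrt(bestVal)
                              else bestVal)
        na <- length(members[[a]]); nb <- length(members[[b]])
        for (c in setdiff(active, c(a, b))) {
            nc <- length(members[[c]])
            cur[a, c] <- cur[c, a] <- if (linkage == "ward")
                ((na + nc) * cur[a, c] + (nb + nc) * cur[b, c] -
                 nc * cur[a, b]) / (na + nb + nc)
            else max(cur[a, c], cur[b, c])
        }
        members[[a]] <- c(members[[a]], members[[b]])
        active <- setdiff(active, b)
        lab[members[[a]]] <- min(members[[a]])
        partitions[[as.character(length(active))]] <- lab
    }
    ## partitions is indexed by the number of clusters after each merge
    list(heights = sort(heights), byK = partitions)
}

## canonical relabeling for partition comparison
canonical <- function(labels) {
    as.integer(factor(labels, levels = unique(labels)))
}

## --- NB exact test enumeration oracle ---------------------------------

nbEnumOracle <- function(kA, kB, sfA, sfB, alpha) {
    K <- kA + kB
    if (K == 0) return(1)
    SA <- sum(sfA); SB <- sum(sfB)
    q <- K / (SA + SB)
    sizeA <- SA^2 / (alpha * sum(sfA^2))
    sizeB <- SB^2 / (alpha * sum(sfB^2))
    probs <- numeric(K + 1)
    for (a in 0:K)
        probs[a + 1] <- dnbinom(a, mu = q * SA, size = sizeA) *
            dnbinom(K - a, mu = q * SB, size = sizeB)
    pObs <- probs[kA + 1]
    sum(probs[probs <= pObs * (1 + 1e-7)]) / sum(probs)
}

## --- GSEA running-sum oracle ------------------------------------------

esOracle <- function(scores, hits, p = 1) {
    N <- length(scores); NH <- sum(hits)
    NR <- sum(abs(scores[hits])^p)
    run <- 0; best <- 0
    for (i in seq_len(N)) {
        run <- run + if (hits[i]) abs(scores[i])^p / NR
                     else -1 / (N - NH)
        if (abs(run) > abs(best)) best <- run
    }
    best
}
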