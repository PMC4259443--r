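#' @include AllClasses.R
NULL

#' Configuration of the synthetic breast-tumor cohort
#'
#' Bundles every knob of the ground-truth generator: cohort composition,
#' negative-binomial expression model, planted subtype markers, cis
#' lncRNA-mRNA pairs, lncRNA/mRNA exon overlap, promoter chromatin truth
#' and survival model. Defaults emulate the structures a bulk RNA-seq
#' breast-cancer cohort analysis assumes: four latent expression subtypes
#' with proportions echoing the luminal-A / luminal-B / basal / HER2
#' mixture of clinical series, NB dispersion 0.2, four-fold subtype
#' markers, cis pairs with latent log-scale correlation 0.8, and
#' exponential survival with subtype- and gene-dependent hazards.
#'
#' @param nSamples Cohort size (default 200).
#' @param nClusters Number of latent subtypes (default 4).
#' @param clusterProportions Mixture proportions (must sum to 1).
#' @param nMrna,nLnc Number of coding genes / lncRNAs (800, 300).
#' @param dispersion NB dispersion alpha (0.2).
#' @param markerLog2FC log2 effect of a marker gene in its subtype (2.0,
#'   i.e. four-fold).
#' @param nMarkerLnc,nMarkerMrna Markers per subtype (25 lncRNAs, 50
#'   mRNAs).
#' @param nCisPairs Planted neighboring lncRNA-mRNA pairs (40).
#' @param cisRho Latent log-scale correlation of a cis pair (0.8).
#' @param lncOverlapFraction Fraction of lncRNAs whose exons overlap a
#'   coding exon (0.15), exercising length masking and union counting.
#' @param bivalentFraction Fraction of lncRNAs planted bivalent
#'   (H3K4me3 + H3K27me3) in the first context (0.1).
#' @param enhancerFraction Fraction of lncRNAs planted H3K27ac-marked in
#'   at least one context (0.6).
#' @param markLossFraction Fraction of H3K27me3-marked genes that lose the
#'   mark in the second context (0.5).
#' @param baselineHazard Exponential baseline hazard per day (1/2000).
#' @param clusterHazardRatios Hazard ratio per subtype.
#' @param nPrognostic Planted prognostic lncRNAs (10).
#' @param prognosticBeta Log hazard ratio per SD of expression (0.5).
#' @param censoringRate Target fraction of censored subjects (0.3).
#' @param seed Master RNG seed; every emitted file is a deterministic
#'   function of the config.
#' @return A validated list of class `CohortConfig`.
#' @export
cohortConfig <- function(nSamples = 200, nClusters = 4,
                         clusterProportions = c(0.46, 0.25, 0.19, 0.10),
                         nMrna = 800, nLnc = 300, dispersion = 0.2,
                         markerLog2FC = 2.0, nMarkerLnc = 25,
                         nMarkerMrna = 50, nCisPairs = 40, cisRho = 0.8,
                         lncOverlapFraction = 0.15,
                         bivalentFraction = 0.1, enhancerFraction = 0.6,
                         markLossFraction = 0.5,
                         baselineHazard = 1 / 2000,
                         clusterHazardRatios = c(1, 1.5, 0.6, 1.2),
                         nPrognostic = 10, prognosticBeta = 0.5,
                         censoringRate = 0.3, seed = 1) {
    cfg <- list(nSamples = nSamples, nClusters = nClusters,
                clusterProportions = clusterProportions, nMrna = nMrna,
                nLnc = nLnc, dispersion = dispersion,
                markerLog2FC = markerLog2FC, nMarkerLnc = nMarkerLnc,
                nMarkerMrna = nMarkerMrna, nCisPairs = nCisPairs,
                cisRho = cisRho, lncOverlapFraction = lncOverlapFraction,
                bivalentFraction = bivalentFraction,
                enhancerFraction = enhancerFraction,
                markLossFraction = markLossFraction,
                baselineHazard = baselineHazard,
                clusterHazardRatios = clusterHazardRatios,
                nPrognostic = nPrognostic,
                prognosticBeta = prognosticBeta,
                censoringRate = censoringRate, seed = seed)
    stopifnot(abs(sum(cfg$clusterProportions) - 1) < 1e-8,
              length(cfg$clusterProportions) == cfg$nClusters,
              length(cfg$clusterHazardRatios) == cfg$nClusters,
              cfg$cisRho > 0, cfg$cisRho < 1,
              cfg$nSamples > 0, cfg$nMrna > 0, cfg$nLnc > 0)
    class(cfg) <- "CohortConfig"
    cfg
}

#' @export
print.CohortConfig <- function(x, ...) {
    cat("CohortConfig:", x$nSamples, "samples,", x$nClusters, "subtypes,",
        x$nMrna, "mRNAs +", x$nLnc, "lncRNAs (seed", paste0(x$seed, ")\n"))
    invisible(x)
}

.LNC_OVERLAP_BIOTYPES <- c("antisense", "sense_overlapping")
.LNC_FREE_BIOTYPES <- c("lincRNA", "processed_transcript",
                        "sense_intronic", "three_prime_overlapping_ncRNA")

#' Generate a synthetic gene annotation
#'
#' Lays coding genes and lncRNAs out on two synthetic chromosomes in
#' well-spaced slots, makes each planted cis pair genomically adjacent
#' (so the basal-plus-extension rule recovers it), gives the configured
#' fraction of lncRNAs an exon overlapping a coding exon (antisense /
#' sense-overlapping biotypes), and draws the remaining lncRNA biotypes
#' over the intergenic categories. Optionally writes the model as GTF.
#'
#' @param cfg A [cohortConfig()].
#' @param gtf Optional output GTF path.
#' @return List with `geneModel` (the truth [GeneModel-class]),
#'   `cisPairs` (`data.frame` of `lnc_gene_id`, `coding_gene_id`),
#'   `overlapLnc` (ids of overlap-planted lncRNAs) and `gtf`.
#' @export
generateAnnotation <- function(cfg, gtf = NULL) {
    old <- globalSeed(); on.exit(restoreSeed(old), add = TRUE)
    set.seed(cfg$seed)
    nOverlap <- floor(cfg$lncOverlapFraction * cfg$nLnc)
    nFree <- cfg$nLnc - nOverlap
    nCis <- min(cfg$nCisPairs, nFree, cfg$nMrna)
    nSlots <- cfg$nMrna + nFree
    mrnaIds <- sprintf("MRNA%04d", seq_len(cfg$nMrna))
    lncIds <- sprintf("LNC%04d", seq_len(cfg$nLnc))

    ## slot layout: cis pairs occupy adjacent slots (lnc then its partner)
    slotType <- c(rep("cisPair", nCis),
                  sample(c(rep("mrna", cfg$nMrna - nCis),
                           rep("lnc", nFree - nCis))))
    freeLnc <- lncIds[seq_len(nFree)]
    ovLnc <- lncIds[nFree + seq_len(nOverlap)]
    cisLnc <- freeLnc[seq_len(nCis)]
    otherLnc <- if (nFree > nCis) freeLnc[(nCis + 1):nFree] else character()
    cisMrna <- mrnaIds[seq_len(nCis)]
    otherMrna <- mrnaIds[setdiff(seq_len(cfg$nMrna), seq_len(nCis))]

    specs <- list()  # per gene: id, biotype, chrom, strand, tss slot pos
    li <- 1L; mi <- 1L; ci <- 1L
    pos <- 50000; chromIdx <- 1L
    half <- ceiling(length(slotType) / 2)
    slotCount <- 0L
    addGene <- function(id, biotype, chrom, tssPos) {
        specs[[length(specs) + 1L]] <<- list(id = id, biotype = biotype,
                                             chrom = chrom, tss = tssPos)
    }
    for (st in slotType) {
        slotCount <- slotCount + 1L
        if (slotCount > half && chromIdx == 1L) {
            chromIdx <- 2L; pos <- 50000
        }
        chrom <- paste0("chrS", chromIdx)
        if (st == "cisPair") {
            addGene(cisLnc[ci], sample(.LNC_FREE_BIOTYPES, 1L,
                                       prob = c(0.7, 0.2, 0.05, 0.05)),
                    chrom, pos)
            pos <- pos + round(stats::runif(1, 22000, 40000))
            addGene(cisMrna[ci], "protein_coding", chrom, pos)
            ci <- ci + 1L
        } else if (st == "mrna") {
            addGene(otherMrna[mi], "protein_coding", chrom, pos)
            mi <- mi + 1L
        } else {
            addGene(otherLnc[li], sample(.LNC_FREE_BIOTYPES, 1L,
                                         prob = c(0.7, 0.2, 0.05, 0.05)),
                    chrom, pos)
            li <- li + 1L
        }
        pos <- pos + round(stats::runif(1, 22000, 40000))
    }
    ## exon structures
    exonRows <- list()
    codingFirstExon <- list()  # chrom/start/end/strand of first exon
    for (sp in specs) {
        strand <- sample(c("+", "-"), 1L)
        if (sp$biotype == "protein_coding") {
            nEx <- sample(3:6, 1L)
            wid <- round(stats::runif(nEx, 120, 400))
            gap <- round(stats::runif(nEx - 1, 300, 2000))
        } else {
            nEx <- sample(1:3, 1L)
            wid <- round(stats::runif(nEx, 200, 1500))
            gap <- if (nEx > 1) round(stats::runif(nEx - 1, 300, 2000))
                   else integer()
        }
        offs <- cumsum(c(0, head(wid, -1) + gap))
        if (strand == "+") {
            st <- sp$tss + offs
        } else {
            en <- sp$tss - offs
            st <- en - wid + 1
        }
        en <- st + wid - 1
        o <- order(st)
        exonRows[[length(exonRows) + 1L]] <- data.frame(
            gene_id = sp$id, biotype = sp$biotype, chrom = sp$chrom,
            start = st[o], end = en[o], strand = strand,
            stringsAsFactors = FALSE)
        if (sp$biotype == "protein_coding")
            codingFirstExon[[sp$id]] <- list(chrom = sp$chrom,
                                             start = st[o][1L],
                                             end = en[o][1L],
                                             strand = strand)
    }
    ## overlap-planted lncRNAs sit antisense on a coding exon
    hosts <- sample(names(codingFirstExon), nOverlap)
    for (i in seq_len(nOverlap)) {
        h <- codingFirstExon[[hosts[i]]]
        mid <- floor((h$start + h$end) / 2)
        st <- mid; en <- mid + round(stats::runif(1, 400, 900))
        strand <- if (h$strand == "+") "-" else "+"
        bio <- sample(.LNC_OVERLAP_BIOTYPES, 1L, prob = c(0.8, 0.2))
        exonRows[[length(exonRows) + 1L]] <- data.frame(
            gene_id = ovLnc[i], biotype = bio, chrom = h$chrom,
            start = st, end = en, strand = strand,
            stringsAsFactors = FALSE)
    }
    ex <- do.call(rbind, exonRows)
    gr <- GRanges(ex$chrom, IRanges(ex$start, ex$end), strand = ex$strand)
    gm <- makeGeneModel(ex$gene_id, ex$biotype, ex$gene_id, gr)
    if (!is.null(gtf)) writeGeneAnnotation(gm, gtf)
    list(geneModel = gm,
         cisPairs = data.frame(lnc_gene_id = cisLnc,
                               coding_gene_id = cisMrna,
                               stringsAsFactors = FALSE),
         overlapLnc = ovLnc, gtf = gtf)
}

#' Generate counts, clinical data and ground truth for a cohort
#'
#' Draws negative-binomial counts with log2 mean = gene baseline +
#' subtype marker effect + shared cis latent factor + biological noise,
#' multiplied by a four-fold range of library sizes. The cis factor is
#' scaled so that the *observed* log-scale correlation of a planted pair
#' approaches `cisRho` (the scaling accounts for the biological and NB
#' noise variance). Survival times are exponential with subtype hazard
#' ratios and planted per-gene log hazards on standardized latent
#' expression; censoring is independent exponential calibrated to the
#' target censoring rate.
#'
#' @param cfg A [cohortConfig()].
#' @param annotation Result of [generateAnnotation()] for the same config.
#' @return List with `counts` (integer matrix genes x samples),
#'   `clinical` (`data.frame`: sample, subtype, er, pr, her2, os_time,
#'   os_event) and `truth` (cluster assignment, marker lists, cis pairs
#'   with rho, prognostic genes and betas, library sizes, latent log2
#'   means of prognostic genes).
#' @export
generateCohort <- function(cfg, annotation) {
    old <- globalSeed(); on.exit(restoreSeed(old), add = TRUE)
    set.seed(cfg$seed + 1L)
    gm <- annotation$geneModel
    ids <- geneIds(gm)
    lnc <- isLncRNA(gm)
    lncIds <- ids[lnc]; mrnaIds <- ids[!lnc]
    n <- cfg$nSamples
    samples <- sprintf("S%03d", seq_len(n))

    ## subtype assignment; every subtype gets at least 3 samples
    repeat {
        cluster <- sample.int(cfg$nClusters, n, replace = TRUE,
                              prob = cfg$clusterProportions)
        if (all(tabulate(cluster, cfg$nClusters) >= 3L)) break
    }
    names(cluster) <- samples

    base <- stats::setNames(numeric(length(ids)), ids)
    base[mrnaIds] <- stats::runif(length(mrnaIds), 3, 9)
    base[lncIds] <- stats::runif(length(lncIds), 0.5, 6)
    ## a third of the lncRNAs are quiescent, so the prevalence filter has
    ## something to remove, as in real catalogues
    silent <- sample(lncIds, floor(0.35 * length(lncIds)))
    base[silent] <- stats::runif(length(silent), -7, -3.5)

    ## cis pairs get a comfortable baseline so NB noise stays moderate
    cis <- annotation$cisPairs
    cisGenes <- c(cis$lnc_gene_id, cis$coding_gene_id)
    base[cisGenes] <- pmax(base[cisGenes], stats::runif(length(cisGenes),
                                                        5, 8))
    ## markers: disjoint, outside the cis set
    freeL <- setdiff(lncIds, cisGenes)
    freeM <- setdiff(mrnaIds, cisGenes)
    markerLnc <- split(sample(freeL, cfg$nMarkerLnc * cfg$nClusters),
                       rep(seq_len(cfg$nClusters), each = cfg$nMarkerLnc))
    markerMrna <- split(sample(freeM, cfg$nMarkerMrna * cfg$nClusters),
                        rep(seq_len(cfg$nClusters), each = cfg$nMarkerMrna))
    markerOf <- stats::setNames(rep(0L, length(ids)), ids)
    for (k in seq_len(cfg$nClusters)) {
        markerOf[markerLnc[[k]]] <- k
        markerOf[markerMrna[[k]]] <- k
    }
    ## markers are drawn from the expressed landscape: keep them above the
    ## quiescent range
    mk <- names(markerOf)[markerOf > 0L]
    base[mk] <- pmax(base[mk], stats::runif(length(mk), 1.5, 6))
    ## prognostic lncRNAs: outside markers and cis pairs
    progPool <- setdiff(freeL, unlist(markerLnc))
    prognostic <- sample(progPool, cfg$nPrognostic)
    base[prognostic] <- pmax(base[prognostic], stats::runif(cfg$nPrognostic,
                                                            4, 7))

    sigmaBio <- 0.25                       # per-gene log2 biological noise
    sigmaProg <- 1.2                       # prognostic-module log2 SD: wide
                                           # patient-to-patient variation
    rhoProg <- 0.8                         # gene-to-module correlation^2
    nbLogVar <- function(mu) (1 / mu + cfg$dispersion) / log(2)^2
    lib <- 2^stats::runif(n, -1, 1)        # 4x library-size range

    logMu <- matrix(rep(base, n), length(ids), n,
                    dimnames = list(ids, samples))
    eff <- matrix(0, length(ids), n)
    for (k in seq_len(cfg$nClusters))
        eff[markerOf == k, cluster == k] <- cfg$markerLog2FC
    logMu <- logMu + eff
    logMu <- logMu + matrix(stats::rnorm(length(logMu), 0, sigmaBio),
                            nrow(logMu))
    ## prognostic lncRNAs form a co-expressed module tracking one latent
    ## risk score; the hazard acts on the module score, so each member
    ## gene carries the planted marginal log-hazard without the signal
    ## being washed out across genes
    riskScore <- stats::rnorm(n)
    logMu[prognostic, ] <- logMu[prognostic, ] +
        sigmaProg * (sqrt(rhoProg) * rep(riskScore,
                                         each = cfg$nPrognostic) +
                     sqrt(1 - rhoProg) *
                     stats::rnorm(cfg$nPrognostic * n))
    ## shared latent factor per cis pair, scaled for the observed log
    ## correlation: rho = a^2 / (a^2 + sigmaBio^2 + nbVar)
    for (i in seq_len(nrow(cis))) {
        pair <- c(cis$lnc_gene_id[i], cis$coding_gene_id[i])
        vNoise <- sigmaBio^2 + mean(nbLogVar(2^base[pair]))
        a <- sqrt(cfg$cisRho / (1 - cfg$cisRho) * vNoise)
        z <- stats::rnorm(n)
        logMu[pair, ] <- logMu[pair, ] + rep(a * z, each = 2)
    }
    mu <- 2^logMu * rep(lib, each = nrow(logMu))
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / cfg$dispersion),
                     nrow(mu), dimnames = dimnames(mu))

    ## survival: exponential with subtype hazards and the planted
    ## log-hazard on the prognostic module score
    linPred <- cfg$prognosticBeta * riskScore
    hr <- cfg$clusterHazardRatios[cluster]
    haz <- cfg$baselineHazard * hr * exp(linPred)
    tDeath <- stats::rexp(n, rate = haz)
    cRate <- mean(haz) * cfg$censoringRate / (1 - cfg$censoringRate)
    tCens <- stats::rexp(n, rate = cRate)
    osTime <- pmax(1, round(pmin(tDeath, tCens)))
    osEvent <- as.integer(tDeath <= tCens)

    subtypeNames <- c("Basal", "HER2E", "LumA", "LumB")[
        seq_len(cfg$nClusters)]
    pam50 <- subtypeNames[cluster]
    flip <- stats::runif(n) < 0.1          # 10% label noise vs truth
    pam50[flip] <- sample(subtypeNames, sum(flip), replace = TRUE)
    erProb <- c(Basal = 0.1, HER2E = 0.3, LumA = 0.95, LumB = 0.9)
    her2Prob <- c(Basal = 0.1, HER2E = 0.9, LumA = 0.1, LumB = 0.25)
    clinical <- data.frame(
        sample = samples, subtype = pam50,
        er = ifelse(stats::runif(n) < erProb[pam50], "positive",
                    "negative"),
        pr = ifelse(stats::runif(n) < erProb[pam50] - 0.05, "positive",
                    "negative"),
        her2 = ifelse(stats::runif(n) < her2Prob[pam50], "positive",
                      "negative"),
        os_time = osTime, os_event = osEvent,
        stringsAsFactors = FALSE)

    cis$rho <- cfg$cisRho
    list(counts = counts, clinical = clinical,
         truth = list(cluster = cluster, markerLnc = markerLnc,
                      markerMrna = markerMrna, cisPairs = cis,
                      prognostic = prognostic,
                      prognosticBeta = cfg$prognosticBeta,
                      libSizes = stats::setNames(lib, samples)))
}

#' Generate ChIP-seq peak files with planted chromatin truth
#'
#' Assigns every gene a boolean mark status per (mark, context) coupled to
#' its expression tier: active marks (H3K4me3, H3K4me2, H3K36me3, H3K27ac)
#' are frequent in the top tertile and rare in the bottom; the repressive
#' H3K27me3/H3K9me3 are the reverse. On top of that it plants the
#' configured bivalent fraction (H3K4me3 + H3K27me3 in the first context),
#' an exact enhancer fraction of lncRNAs (H3K27ac in at least one
#' context), and H3K27me3 loss in the second context for the configured
#' fraction of marked genes, biased toward higher-expressed genes. Peaks
#' are placed on a per-gene "promoter zone" that lies inside the gene's
#' own +/- 5 kb TSS window and outside every other gene's window, so the
#' planted truth is exactly recoverable by [annotateMarks()]; genes with
#' no such zone are forced unmarked everywhere.
#'
#' @param cfg A [cohortConfig()].
#' @param annotation Result of [generateAnnotation()].
#' @param expr Expression matrix used for the tier coupling (e.g. FPKM of
#'   the generated counts).
#' @param dir Optional directory: one BED file per (mark, context) is
#'   written there.
#' @param contexts Names of the two cell contexts.
#' @param window Promoter window half-width (must match the annotation
#'   step; default 5000).
#' @return List with `truth` (logical gene x mark x context array),
#'   `peaks` (list of `GRanges` named `<mark>.<context>`), `files`
#'   (written BED paths or `NULL`) and `zoneless` (genes without a valid
#'   peak zone).
#' @export
generatePeaks <- function(cfg, annotation, expr, dir = NULL,
                          contexts = c("HMEC", "MCF7"), window = 5000) {
    old <- globalSeed(); on.exit(restoreSeed(old), add = TRUE)
    set.seed(cfg$seed + 2L)
    gm <- annotation$geneModel
    ids <- geneIds(gm)
    lncIds <- ids[isLncRNA(gm)]
    med <- stats::setNames(rep(0, length(ids)), ids)
    common <- intersect(ids, rownames(expr))
    med[common] <- apply(expr[common, , drop = FALSE], 1L, stats::median)
    tier <- cut(rank(med, ties.method = "first"), 3L, labels = FALSE)
    names(tier) <- ids

    active <- c("H3K4me3", "H3K4me2", "H3K36me3")
    pActive <- c(0.15, 0.5, 0.9)     # by tier, low -> high expression
    pRepress <- c(0.8, 0.4, 0.15)
    marks <- .HISTONE_MARKS
    a <- array(FALSE, dim = c(length(ids), length(marks), 2L),
               dimnames = list(ids, marks, contexts))
    for (cx in 1:2) {
        for (mk in active)
            a[, mk, cx] <- stats::runif(length(ids)) < pActive[tier]
        a[, "H3K9me3", cx] <-
            stats::runif(length(ids)) < 0.6 * pRepress[tier]
    }
    ## H3K27me3 is drawn in context 1; planted bivalent lncRNAs (both
    ## H3K4me3 and H3K27me3) are added there first so that the context-2
    ## copy below sees the final context-1 state
    a[, "H3K27me3", 1L] <- stats::runif(length(ids)) < pRepress[tier]
    nBiv <- floor(cfg$bivalentFraction * length(lncIds))
    biv <- sample(lncIds, nBiv)
    a[biv, "H3K4me3", 1L] <- TRUE
    a[biv, "H3K27me3", 1L] <- TRUE
    ## the configured fraction of marked genes lose H3K27me3 in context 2
    ## (no gains), loss biased toward higher-expressed genes
    markedIdx <- which(a[, "H3K27me3", 1L])
    nLose <- floor(cfg$markLossFraction * length(markedIdx))
    lose <- if (nLose > 0)
        sample(markedIdx, nLose, prob = rank(med[markedIdx]))
    else integer()
    a[, "H3K27me3", 2L] <- a[, "H3K27me3", 1L]
    a[lose, "H3K27me3", 2L] <- FALSE

    ## exact enhancer fraction among lncRNAs: H3K27ac in >= 1 context
    nEnh <- floor(cfg$enhancerFraction * length(lncIds))
    enh <- sample(lncIds, nEnh, prob = rank(med[lncIds]))
    a[lncIds, "H3K27ac", ] <- FALSE
    inA <- stats::runif(nEnh) < 0.8
    inB <- stats::runif(nEnh) < 0.7
    neither <- !inA & !inB
    inA[neither] <- TRUE
    a[enh, "H3K27ac", 1L][inA] <- TRUE
    a[enh, "H3K27ac", 2L][inB] <- TRUE
    ## mRNAs keep the tier rule for H3K27ac
    mrnaIds <- setdiff(ids, lncIds)
    for (cx in 1:2)
        a[mrnaIds, "H3K27ac", cx] <-
            stats::runif(length(mrnaIds)) < pActive[tier[mrnaIds]]

    ## promoter zones; genes without one are unmarked everywhere
    zone <- promoterZones(gm, window)
    zoneless <- ids[is.na(zone$start)]
    a[zoneless, , ] <- FALSE

    peaks <- list()
    files <- if (is.null(dir)) NULL else character()
    if (!is.null(dir) && !dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    for (cx in 1:2) for (mk in marks) {
        sel <- which(a[, mk, cx])
        gr <- if (length(sel))
            GRanges(zone$chrom[sel], IRanges(zone$start[sel],
                                             zone$end[sel]))
        else GRanges()
        gr <- GenomicRanges::sort(gr)
        metadata(gr)$mark <- mk
        metadata(gr)$context <- contexts[cx]
        nm <- paste0(mk, ".", contexts[cx])
        peaks[[nm]] <- gr
        if (!is.null(dir)) {
            f <- file.path(dir, paste0(mk, "_", contexts[cx], ".bed"))
            rtracklayer::export(gr, f, format = "BED")
            files <- c(files, f)
        }
    }
    list(truth = a, peaks = peaks, files = files, zoneless = zoneless)
}

#' Generate a synthetic gene-set collection
#'
#' Builds a GMT-style collection over the cohort's mRNAs: one set per
#' subtype holding that subtype's planted marker mRNAs (true signal for
#' the enrichment screen) plus `nRandom` sets of genes drawn at random
#' (null sets).
#'
#' @param cfg A [cohortConfig()].
#' @param cohort Result of [generateCohort()].
#' @param nRandom Number of null sets (default 20).
#' @param setSize Size of each null set (default 40).
#' @param gmt Optional output GMT path.
#' @return Named list of gene-id vectors (written to `gmt` when given).
#' @export
generateGeneSets <- function(cfg, cohort, nRandom = 20, setSize = 40,
                             gmt = NULL) {
    old <- globalSeed(); on.exit(restoreSeed(old), add = TRUE)
    set.seed(cfg$seed + 3L)
    sets <- cohort$truth$markerMrna
    names(sets) <- paste0("SUBTYPE", seq_along(sets), "_MARKERS")
    mrna <- grep("^MRNA", rownames(cohort$counts), value = TRUE)
    for (i in seq_len(nRandom))
        sets[[sprintf("RANDOM%02d", i)]] <- sample(mrna, setSize)
    if (!is.null(gmt)) writeGmt(sets, gmt)
    sets
}

## per-gene peak interval inside the own TSS window and outside all other
## genes' windows; NA when no room
promoterZones <- function(gm, window) {
    tssGr <- tssPositions(gm)
    n <- length(tssGr)
    win <- GRanges(seqnames(tssGr),
                   IRanges(pmax(1L, start(tssGr) - window),
                           start(tssGr) + window))
    inner <- GRanges(seqnames(tssGr),
                     IRanges(pmax(1L, start(tssGr) - window + 1000L),
                             start(tssGr) + window - 1000L))
    chrom <- as.character(seqnames(tssGr))
    zs <- rep(NA_integer_, n); ze <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
        free <- GenomicRanges::setdiff(inner[i], win[-i],
                                       ignore.strand = TRUE)
        free <- free[width(free) >= 700]
        if (!length(free)) next
        s <- start(free)[1L]
        zs[i] <- s + 50L
        ze[i] <- s + 650L
    }
    list(chrom = chrom, start = zs, end = ze)
}
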