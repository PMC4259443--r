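smallCfg <- function(...) {
    cohortConfig(nSamples = 40, nMrna = 80, nLnc = 40, nMarkerLnc = 5,
                 nMarkerMrna = 8, nCisPairs = 6, nPrognostic = 3,
                 seed = 11, ...)
}

test_that("the config validates its invariants", {
    expect_error(cohortConfig(clusterProportions = c(0.5, 0.5)),
                 "length|proportions|cluster")
    expect_error(cohortConfig(cisRho = 1.2))
    expect_s3_class(smallCfg(), "CohortConfig")
})

test_that("annotation generation honors the overlap fraction and
           round-trips through GTF", {
    cfg0 <- smallCfg(lncOverlapFraction = 0)
    ann0 <- generateAnnotation(cfg0)
    ml0 <- maskedLengths(ann0$geneModel)
    expect_equal(ml0$masked_length, ml0$raw_length)
    cfg1 <- smallCfg(lncOverlapFraction = 1)
    suppressWarnings(ann1 <- generateAnnotation(cfg1))
    ml1 <- maskedLengths(ann1$geneModel)
    lnc1 <- isLncRNA(ann1$geneModel)[ml1$gene_id]
    expect_true(all(ml1$masked_length[lnc1] < ml1$raw_length[lnc1]))
    ## emitted GTF re-parses into the truth records
    gtf <- withr::local_tempfile(fileext = ".gtf")
    ann <- generateAnnotation(smallCfg(), gtf = gtf)
    gm2 <- readGeneAnnotation(gtf)
    ord <- match(geneIds(ann$geneModel), geneIds(gm2))
    expect_false(anyNA(ord))
    expect_identical(geneBiotypes(ann$geneModel),
                     geneBiotypes(gm2)[ord])
    expect_equal(ann$geneModel@genes$tss, gm2@genes$tss[ord])
    ## cis pairs are recoverable by the neighbor rule
    nb <- assignNeighbors(ann$geneModel)
    key <- paste(nb$lnc_gene_id, nb$coding_gene_id)
    expect_true(all(paste(ann$cisPairs$lnc_gene_id,
                          ann$cisPairs$coding_gene_id) %in% key))
})

test_that("cohort generation is seed-deterministic and count moments
           match the NB model", {
    cfg <- smallCfg()
    ann <- generateAnnotation(cfg)
    a <- generateCohort(cfg, ann)
    b <- generateCohort(cfg, ann)
    expect_identical(a$counts, b$counts)
    expect_identical(a$clinical, b$clinical)
    ## near-Poisson limit: variance close to mean for a flat gene
    cfgP <- smallCfg(dispersion = 1e-4, markerLog2FC = 0)
    annP <- generateAnnotation(cfgP)
    cohP <- generateCohort(cfgP, annP)
    ## pick well-expressed non-cis genes and undo library sizes
    lib <- cohP$truth$libSizes
    z <- sweep(cohP$counts, 2, lib, "/")
    free <- setdiff(rownames(z), c(cohP$truth$cisPairs$lnc_gene_id,
                                   cohP$truth$cisPairs$coding_gene_id,
                                   cohP$truth$prognostic))
    mid <- free[rowMeans(z[free, ]) > 50]
    mu <- rowMeans(z[mid, ])
    ratio <- apply(z[mid, ], 1, var) / mu
    ## with the NB dispersion off, the only excess over Poisson
    ## (variance/mean = 1) is the small log-normal biological noise;
    ## at dispersion 0.2 the same statistic would sit near 0.2
    expect_lt(median((ratio - 1) / mu), 0.08)
    ## no cluster effect: clustering cannot beat chance
    cfg0 <- smallCfg(markerLog2FC = 0)
    ann0 <- generateAnnotation(cfg0)
    coh0 <- generateCohort(cfg0, ann0)
    sf <- estimateSizeFactors(coh0$counts + 1L)
    v <- vstTransform(coh0$counts, sf,
                      fitDispersions(coh0$counts + 1L, sf,
                                     rep("all", cfg0$nSamples)))
    lab <- hierCluster(v[grepl("^LNC", rownames(v)), ], "euclidean",
                       "ward", 4)
    ari <- mclust::adjustedRandIndex(lab, coh0$truth$cluster)
    expect_lt(abs(ari), 0.15)
})

test_that("planted cis pairs reach the target log-scale correlation at
           large n", {
    cfg <- cohortConfig(nSamples = 2000, nMrna = 60, nLnc = 30,
                        nMarkerLnc = 2, nMarkerMrna = 4, nCisPairs = 10,
                        nPrognostic = 2, seed = 31)
    ann <- generateAnnotation(cfg)
    coh <- generateCohort(cfg, ann)
    lg <- log2(1 + sweep(coh$counts, 2, coh$truth$libSizes, "/"))
    rs <- vapply(seq_len(nrow(coh$truth$cisPairs)), function(i)
        cor(lg[coh$truth$cisPairs$lnc_gene_id[i], ],
            lg[coh$truth$cisPairs$coding_gene_id[i], ]), 1)
    expect_true(all(abs(rs - cfg$cisRho) <= 0.1))
})

test_that("peak generation plants recoverable truth and respects the
           loss fraction", {
    cfg <- smallCfg()
    ann <- generateAnnotation(cfg)
    coh <- generateCohort(cfg, ann)
    ml <- suppressWarnings(maskedLengths(ann$geneModel))
    fp <- computeFpkm(coh$counts[ml$gene_id[ml$masked_length > 0], ],
                      ml)
    dir <- withr::local_tempdir()
    pk <- generatePeaks(cfg, ann, fp, dir = dir)
    ## emitted BED files re-annotate to exactly the planted truth
    peaks <- lapply(pk$files, function(f) {
        parts <- strsplit(sub("\\.bed$", "", basename(f)), "_")[[1]]
        readPeakBed(f, parts[1], parts[2])
    })
    ann2 <- annotateMarks(ann$geneModel, peaks)
    expect_identical(ann2@marked[dimnames(pk$truth)[[1]], ,
                                 dimnames(pk$truth)[[3]]],
                     pk$truth)
    ## loss fraction 0: nothing lost; 1: nothing retained
    pk0 <- generatePeaks(smallCfg(markLossFraction = 0), ann, fp)
    t0 <- pk0$truth
    expect_true(all(t0[, "H3K27me3", 1] == t0[, "H3K27me3", 2]))
    pk1 <- generatePeaks(smallCfg(markLossFraction = 1), ann, fp)
    t1 <- pk1$truth
    expect_false(any(t1[, "H3K27me3", 1] & t1[, "H3K27me3", 2]))
})

test_that("all emitted files are byte-identical under a fixed seed", {
    cfg <- smallCfg()
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    emit <- function(d) {
        ann <- generateAnnotation(cfg, gtf = file.path(d, "ann.gtf"))
        coh <- generateCohort(cfg, ann)
        writeMatrixTsv(coh$counts, file.path(d, "counts.tsv"))
        writeTableTsv(coh$clinical, file.path(d, "clinical.tsv"))
        ml <- suppressWarnings(maskedLengths(ann$geneModel))
        fp <- computeFpkm(coh$counts[ml$gene_id[ml$masked_length > 0], ],
                          ml)
        generatePeaks(cfg, ann, fp, dir = file.path(d, "peaks"))
        writeGmt(generateGeneSets(cfg, coh), file.path(d, "sets.gmt"))
    }
    emit(d1); emit(d2)
    f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
    f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
    expect_equal(basename(f1), basename(f2))
    expect_equal(unname(tools::md5sum(sort(f1))),
                 unname(tools::md5sum(sort(f2))))
})
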