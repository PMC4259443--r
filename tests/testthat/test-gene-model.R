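test_that("GTF exons are merged per gene with a strand-aware TSS", {
    gtf <- withr::local_tempfile(fileext = ".gtf")
    writeLines(c(
        paste0("chr1\tx\texon\t101\t200\t.\t+\t.\t",
               'gene_id "G1"; gene_name "G1"; gene_type "protein_coding";'),
        paste0("chr1\tx\texon\t301\t400\t.\t+\t.\t",
               'gene_id "G1"; gene_name "G1"; gene_type "protein_coding";'),
        paste0("chr1\tx\texon\t101\t200\t.\t+\t.\t",
               'gene_id "G2"; gene_name "G2"; gene_type "lincRNA";'),
        paste0("chr1\tx\texon\t151\t250\t.\t+\t.\t",
               'gene_id "G2"; gene_name "G2"; gene_type "lincRNA";'),
        paste0("chr1\tx\texon\t500\t600\t.\t-\t.\t",
               'gene_id "G3"; gene_name "G3"; gene_type "antisense";')),
        gtf)
    gm <- readGeneAnnotation(gtf)
    expect_setequal(geneIds(gm), c("G1", "G2", "G3"))
    ex1 <- exonsByGene(gm)[["G1"]]
    expect_equal(start(ex1), c(101L, 301L))
    expect_equal(end(ex1), c(200L, 400L))
    expect_equal(gm@genes$tss[gm@genes$gene_id == "G1"], 101L)
    ## two overlapping exon lines merge into one interval of length 150
    ex2 <- exonsByGene(gm)[["G2"]]
    expect_equal(length(ex2), 1L)
    expect_equal(sum(width(ex2)), 150L)
    ## minus-strand TSS is the maximal end
    expect_equal(gm@genes$tss[gm@genes$gene_id == "G3"], 600L)
    expect_false(isLncRNA(gm)[["G1"]])
    expect_true(all(isLncRNA(gm)[c("G2", "G3")]))
})

test_that("unknown biotypes are skipped with a warning, absent gene_id errors", {
    gtf <- withr::local_tempfile(fileext = ".gtf")
    writeLines(c(
        paste0("chr1\tx\texon\t101\t200\t.\t+\t.\t",
               'gene_id "G1"; gene_type "protein_coding";'),
        paste0("chr1\tx\texon\t301\t400\t.\t+\t.\t",
               'gene_id "GX"; gene_type "rRNA";')), gtf)
    expect_warning(gm <- readGeneAnnotation(gtf), "unknown biotype")
    expect_identical(geneIds(gm), "G1")
})

test_that("random gene models round-trip through the GTF writer/reader", {
    set.seed(101)
    for (rep in 1:3) {
        gm <- randomGeneModel(nCoding = 30, nLnc = 20, maxPos = 50000)
        gtf <- withr::local_tempfile(fileext = ".gtf")
        writeGeneAnnotation(gm, gtf)
        gm2 <- readGeneAnnotation(gtf)
        ord <- match(geneIds(gm), geneIds(gm2))
        expect_false(anyNA(ord))
        expect_identical(geneBiotypes(gm), geneBiotypes(gm2)[ord])
        expect_equal(gm@genes$tss, gm2@genes$tss[ord])
        for (g in geneIds(gm))
            expect_equal(IRanges::ranges(exonsByGene(gm)[[g]]),
                         IRanges::ranges(exonsByGene(gm2)[[g]]))
    }
})

test_that("masked lengths match hand examples", {
    ex <- data.frame(gene_id = c("C1", "L1"),
                     biotype = c("protein_coding", "lincRNA"),
                     chrom = "c1", start = c(101, 151), end = c(200, 250),
                     strand = "+")
    gm <- lncScape:::makeGeneModel(ex$gene_id, ex$biotype, ex$gene_id,
        GRanges(ex$chrom, IRanges(ex$start, ex$end), strand = ex$strand))
    ml <- suppressWarnings(maskedLengths(gm))
    ml <- ml[order(ml$gene_id), ]
    ## both genes span 100 bases and share 50: half-overlap symmetry
    expect_equal(ml$raw_length, c(100L, 100L))
    expect_equal(ml$masked_length, c(50L, 50L))
    ## a lone coding exon keeps its full length
    gm1 <- lncScape:::makeGeneModel(c("C1", "L1"),
        c("protein_coding", "lincRNA"), c("C1", "L1"),
        GRanges("c1", IRanges(c(101, 1000), c(200, 1100))))
    ml1 <- maskedLengths(gm1)
    expect_equal(ml1$masked_length, ml1$raw_length)
    expect_equal(ml1$masked_length[ml1$gene_id == "C1"], 100L)
})

test_that("masked lengths equal the per-base brute-force mask", {
    set.seed(42)
    for (rep in 1:25) {
        gm <- randomGeneModel(nCoding = 4, nLnc = 4, maxPos = 1500)
        ml <- suppressWarnings(maskedLengths(gm))
        expect_equal(ml$masked_length, unname(bruteMaskedLengths(gm)))
        expect_equal(ml$raw_length,
                     unname(sum(width(exonsByGene(gm)))))
    }
})

test_that("cross-class overlap bases are counted once per overlapping gene", {
    set.seed(7)
    gm <- randomGeneModel(nCoding = 6, nLnc = 6, maxPos = 1200)
    ml <- suppressWarnings(maskedLengths(gm))
    lnc <- isLncRNA(gm)
    exl <- exonsByGene(gm)
    perGeneOverlap <- vapply(seq_along(exl), function(i) {
        other <- GenomicRanges::reduce(
            unlist(exl[lnc != lnc[i]]), ignore.strand = TRUE)
        sum(width(GenomicRanges::intersect(exl[[i]], other,
                                           ignore.strand = TRUE)))
    }, 1)
    expect_equal(ml$raw_length - ml$masked_length, perGeneOverlap)
})

test_that("neighbor assignment follows the basal-plus-extension rule", {
    mk <- function(df) lncScape:::makeGeneModel(df$gene_id, df$biotype,
        df$gene_id, GRanges(df$chrom, IRanges(df$start, df$end),
                            strand = df$strand))
    ## lncRNA TSS 2 kb upstream of a + strand coding TSS: basal domain
    gm <- mk(data.frame(gene_id = c("C1", "L1"),
                        biotype = c("protein_coding", "lincRNA"),
                        chrom = "c1", start = c(100000, 97500),
                        end = c(101000, 98000), strand = "+"))
    nb <- assignNeighbors(gm)
    expect_equal(nrow(nb), 1L)
    expect_equal(nb$rule, "basal")
    expect_equal(nb$distance, 100000 - 97500)
    ## a 2 Mb gap exceeds the maximum extension
    gmFar <- mk(data.frame(gene_id = c("C1", "L1"),
                           biotype = c("protein_coding", "lincRNA"),
                           chrom = "c1", start = c(3000000, 999000),
                           end = c(3001000, 999500), strand = "+"))
    expect_equal(nrow(assignNeighbors(gmFar)), 0L)
})

test_that("neighbor assignment equals the brute-force domain oracle", {
    set.seed(99)
    for (rep in 1:10) {
        n <- 8
        df <- data.frame(
            gene_id = sprintf("g%02d", 1:n),
            biotype = sample(c("protein_coding", "lincRNA"), n,
                             replace = TRUE, prob = c(0.6, 0.4)),
            chrom = sample(c("c1", "c2"), n, replace = TRUE),
            start = sample.int(3000000, n), strand = sample(c("+", "-"),
                                                            n, TRUE))
        df$end <- df$start + 500
        if (!any(df$biotype == "lincRNA")) df$biotype[1] <- "lincRNA"
        if (!any(df$biotype == "protein_coding"))
            df$biotype[2] <- "protein_coding"
        gm <- lncScape:::makeGeneModel(df$gene_id, df$biotype, df$gene_id,
            GRanges(df$chrom, IRanges(df$start, df$end),
                    strand = df$strand))
        got <- assignNeighbors(gm, maxExtension = 500000)
        want <- bruteNeighbors(gm, maxExtension = 500000)
        rownames(got) <- rownames(want) <- NULL
        expect_equal(got, want)
        ## permutation invariance of the input order
        perm <- sample(length(gm))
        got2 <- assignNeighbors(gm[perm], maxExtension = 500000)
        rownames(got2) <- NULL
        expect_equal(got2, got)
    }
})
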