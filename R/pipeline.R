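#' @include AllClasses.R
NULL

#' Pipeline configuration
#'
#' Collects the input paths and every stage parameter of the end-to-end
#' landscape analysis, validated up front so a run fails before any stage
#' executes. Parameter defaults are the thresholds used throughout the
#' package: FPKM >= 1 in >= 10% of samples for the expressed set, 500
#' consensus runs at 80%/80% resampling, fold change >= 2 with FDR < 0.05
#' for markers, 1% ternarization tails, a +/- 5 kb promoter window and
#' 1000 GSEA permutations.
#'
#' @param gtf,counts,clinical Paths to the annotation GTF, the gene x
#'   sample raw-count TSV and the clinical TSV.
#' @param peaksDir Directory of `<MARK>_<CONTEXT>.bed` peak files
#'   (optional; chromatin stage skipped with an error when missing but
#'   requested).
#' @param gmt Gene-set GMT path (optional: enrichment stage needs it).
#' @param outDir Output directory for stage TSVs and the manifest.
#' @param k Number of subtypes; when `NULL`, chosen by [selectK()] over
#'   `kRange`.
#' @param kRange Candidate k values for selection.
#' @param nRuns,fracSamples,fracFeatures Consensus-clustering settings.
#' @param fpkmMin,fpkmFraction Expression-filter thresholds.
#' @param fcMin,fdrMax Marker thresholds.
#' @param ternaryTail Ternarization tail fraction.
#' @param gseaPerm,gseaWeight GSEA permutations and weight exponent.
#' @param tssWindow Promoter window half-width (bases).
#' @param contexts The two cell contexts expected in `peaksDir`.
#' @param seed Master seed for all stochastic stages.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(gtf, counts, clinical, outDir,
                           peaksDir = NULL, gmt = NULL, k = NULL,
                           kRange = 2:6, nRuns = 500, fracSamples = 0.8,
                           fracFeatures = 0.8, fpkmMin = 1,
                           fpkmFraction = 0.10, fcMin = 2, fdrMax = 0.05,
                           ternaryTail = 0.01, gseaPerm = 1000,
                           gseaWeight = 1, tssWindow = 5000,
                           contexts = c("HMEC", "MCF7"), seed = 1) {
    cfg <- as.list(environment())
    for (f in c("gtf", "counts", "clinical"))
        if (!file.exists(cfg[[f]]))
            stop("input file for '", f, "' not found: ", cfg[[f]])
    if (!is.null(peaksDir) && !dir.exists(peaksDir))
        stop("peaksDir not found: ", peaksDir)
    if (!is.null(gmt) && !file.exists(gmt))
        stop("gmt not found: ", gmt)
    stopifnot(fpkmMin >= 0, fpkmFraction > 0, fpkmFraction <= 1,
              nRuns >= 1, fcMin >= 1, fdrMax > 0, fdrMax <= 1,
              ternaryTail >= 0, ternaryTail < 0.5, gseaPerm >= 1,
              tssWindow > 0, length(contexts) == 2L)
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Run the full lncRNA landscape pipeline
#'
#' Executes the stages in dependency order -- quantify, filter,
#' normalize, cluster, markers, associate, gsea, chromatin, survive --
#' writing each stage's tables under `outDir` and finally a
#' `manifest.json` recording the package version, seed, a parameter hash
#' and the completed stages. A rerun with the same config and seed
#' produces byte-identical outputs. With `resume = TRUE`, stages whose
#' output files already exist are skipped. Stages whose inputs were not
#' configured (no `peaksDir`, no `gmt`) are recorded as skipped.
#'
#' @param config A [pipelineConfig()].
#' @param resume Reuse existing stage outputs (default `FALSE`).
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
runPipeline <- function(config, resume = FALSE) {
    stopifnot(inherits(config, "PipelineConfig"))
    out <- config$outDir
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    pth <- function(...) file.path(out, paste0(...))
    done <- character()
    stage <- function(name, outputs, fun) {
        paths <- vapply(outputs, pth, "")
        if (resume && all(file.exists(paths))) {
            done <<- c(done, name)
            return(invisible(NULL))
        }
        res <- tryCatch(fun(), error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
        done <<- c(done, name)
        res
    }

    ## quantify: gene model, masked lengths, FPKM
    gm <- readGeneAnnotation(config$gtf)
    counts <- readMatrixTsv(config$counts, integer = TRUE)
    clinical <- readTableTsv(config$clinical)
    env <- new.env()
    stage("quantify", c("masked_lengths.tsv", "fpkm.tsv"), function() {
        ml <- maskedLengths(gm)
        common <- intersect(rownames(counts),
                            ml$gene_id[ml$masked_length > 0])
        env$fpkm <- computeFpkm(counts[common, , drop = FALSE],
                                ml[ml$gene_id %in% common, ])
        writeTableTsv(ml, pth("masked_lengths.tsv"))
        writeMatrixTsv(round(env$fpkm, 4), pth("fpkm.tsv"))
    })

    stage("filter", "expressed_genes.tsv", function() {
        keep <- filterLowExpression(env$fpkm, config$fpkmMin,
                                    config$fpkmFraction)
        lnc <- isLncRNA(gm)
        env$expressed <- keep
        env$expressedLnc <- keep[lnc[keep]]
        env$expressedMrna <- keep[!lnc[keep]]
        writeTableTsv(data.frame(gene_id = keep,
                                 class = ifelse(lnc[keep], "lncRNA",
                                                "coding")),
                      pth("expressed_genes.tsv"))
    })

    stage("normalize", c("size_factors.tsv", "vst.tsv"), function() {
        sub <- counts[env$expressed, , drop = FALSE]
        env$sf <- estimateSizeFactors(sub)
        disp <- fitDispersions(sub, env$sf, rep("all", ncol(sub)))
        env$vst <- vstTransform(sub, env$sf, disp)
        env$subCounts <- sub
        writeTableTsv(data.frame(sample = names(env$sf),
                                 size_factor = round(env$sf, 6)),
                      pth("size_factors.tsv"))
        writeMatrixTsv(round(env$vst, 4), pth("vst.tsv"))
    })

    stage("cluster", c("clusters.tsv", "consensus_matrix.tsv",
                       "bic.tsv"), function() {
        lncMat <- env$vst[env$expressedLnc, , drop = FALSE]
        if (is.null(config$k)) {
            sel <- selectK(lncMat, kRange = config$kRange,
                           nRuns = min(config$nRuns, 100),
                           fracSamples = config$fracSamples,
                           fracFeatures = config$fracFeatures,
                           seed = config$seed)
            env$k <- sel$kStar
            bicTab <- sel$table
        } else {
            env$k <- config$k
            bicTab <- data.frame(k = config$k, bic = NA_real_,
                                 flagged = FALSE)
        }
        cm <- runConsensus(lncMat, env$k, nRuns = config$nRuns,
                           fracSamples = config$fracSamples,
                           fracFeatures = config$fracFeatures,
                           seed = config$seed)
        env$clusters <- clusterConsensus(cm, env$k)
        writeTableTsv(data.frame(sample = names(env$clusters),
                                 cluster = env$clusters),
                      pth("clusters.tsv"))
        writeMatrixTsv(round(consensusValues(cm), 4),
                       pth("consensus_matrix.tsv"))
        writeTableTsv(bicTab, pth("bic.tsv"))
    })

    stage("markers", "markers.tsv", function() {
        tabs <- lapply(sort(unique(env$clusters)), function(k) {
            m <- subtypeMarkers(env$subCounts, env$sf, env$clusters, k,
                                fcMin = config$fcMin,
                                fdrMax = config$fdrMax)
            if (nrow(m)) cbind(cluster = k, m) else NULL
        })
        env$markers <- do.call(rbind, tabs)
        if (is.null(env$markers))
            env$markers <- data.frame(cluster = integer(),
                                      gene_id = character())
        env$markers$p_value <- signif(env$markers$p_value, 6)
        env$markers$fdr <- signif(env$markers$fdr, 6)
        env$markers$fold_change <- round(env$markers$fold_change, 4)
        env$markers$mean_norm_target <-
            round(env$markers$mean_norm_target, 4)
        env$markers$mean_norm_rest <- round(env$markers$mean_norm_rest, 4)
        writeTableTsv(env$markers, pth("markers.tsv"))
    })

    stage("associate", c("ternary.tsv", "cis_report.tsv",
                         "neighbors.tsv"), function() {
        lncMat <- env$vst[env$expressedLnc, , drop = FALSE]
        mrnaMat <- env$vst[env$expressedMrna, , drop = FALSE]
        r <- correlationMatrix(lncMat, mrnaMat)
        env$ternary <- ternarize(r, config$ternaryTail)
        nb <- assignNeighbors(gm)
        env$cis <- cisReport(nb, r)
        env$cis$r <- round(env$cis$r, 4)
        writeMatrixTsv(ternaryEntries(env$ternary), pth("ternary.tsv"))
        writeTableTsv(env$cis, pth("cis_report.tsv"))
        writeTableTsv(nb, pth("neighbors.tsv"))
    })

    if (!is.null(config$gmt)) {
        stage("gsea", c("gsea.tsv", "gsea_ternary.tsv"), function() {
            sets <- readGmt(config$gmt)
            phen <- unique(env$markers$gene_id[
                env$markers$gene_id %in% env$expressedLnc])
            if (!length(phen)) phen <- utils::head(env$expressedLnc, 25)
            scr <- gseaScreen(env$vst[env$expressedLnc, , drop = FALSE],
                              env$vst[env$expressedMrna, , drop = FALSE],
                              sets, p = config$gseaWeight,
                              nPerm = config$gseaPerm,
                              seed = config$seed, lncIds = phen)
            env$gsea <- scr
            scr$es <- round(scr$es, 4); scr$nes <- round(scr$nes, 4)
            scr$p_value <- signif(scr$p_value, 6)
            scr$fdr <- signif(scr$fdr, 6)
            writeTableTsv(scr, pth("gsea.tsv"))
            writeMatrixTsv(ternaryEntries(gseaTernaryMatrix(env$gsea)),
                           pth("gsea_ternary.tsv"))
        })
    }

    if (!is.null(config$peaksDir)) {
        stage("chromatin", c("mark_annotation.tsv",
                             "chromatin_summary.tsv"), function() {
            files <- list.files(config$peaksDir, "\\.bed$",
                                full.names = TRUE)
            if (!length(files)) stop("no BED files in peaksDir")
            peaks <- lapply(files, function(f) {
                base <- sub("\\.bed$", "", basename(f))
                parts <- strsplit(base, "_")[[1L]]
                readPeakBed(f, parts[1L],
                            paste(parts[-1L], collapse = "_"))
            })
            ann <- annotateMarks(gm, peaks, window = config$tssWindow)
            env$ann <- ann
            cxs <- dimnames(ann)[[3L]]
            long <- do.call(rbind, lapply(cxs, function(cx) {
                m <- ann@marked[, , cx]
                data.frame(gene_id = rep(rownames(m), ncol(m)),
                           mark = rep(colnames(m), each = nrow(m)),
                           context = cx, marked = as.vector(m))
            }))
            writeTableTsv(long, pth("mark_annotation.tsv"))
            summ <- do.call(rbind, lapply(cxs, function(cx) {
                s <- expressionByMark(env$fpkm[env$expressedLnc, ,
                                               drop = FALSE], ann, cx)
                cbind(context = cx, s)
            }))
            summ[, c("q1", "median", "q3")] <-
                round(summ[, c("q1", "median", "q3")], 4)
            biv <- vapply(cxs, function(cx)
                length(intersect(bivalentGenes(ann, cx),
                                 env$expressedLnc)), 1L)
            env$bivalent <- biv
            env$enhancer <- enhancerLncRNAs(ann, cxs,
                                            genes = env$expressedLnc)
            writeTableTsv(summ, pth("chromatin_summary.tsv"))
        })
    }

    stage("survive", c("survival_clusters.tsv", "cox_screen.tsv"),
          function() {
        km <- kmLogrank(env$clusters, clinical)
        env$km <- km
        writeTableTsv(data.frame(chisq = round(km$chisq, 4), df = km$df,
                                 p = signif(km$p, 6)),
                      pth("survival_clusters.tsv"))
        cox <- coxScreen(env$vst[env$expressedLnc, , drop = FALSE],
                         clinical, fdrMax = config$fdrMax)
        env$cox <- cox
        cox$coef <- round(cox$coef, 5)
        cox$p_value <- signif(cox$p_value, 6)
        cox$fdr <- signif(cox$fdr, 6)
        writeTableTsv(cox, pth("cox_screen.tsv"))
    })

    paramJson <- jsonlite::toJSON(config[setdiff(names(config),
                                                 "outDir")],
                                  auto_unbox = TRUE, digits = NA,
                                  null = "null")
    tmp <- tempfile(); writeLines(paramJson, tmp)
    manifest <- list(
        package = "lncScape",
        version = as.character(utils::packageVersion("lncScape")),
        seed = config$seed,
        parameter_hash = unname(tools::md5sum(tmp)),
        stages = done)
    unlink(tmp)
    jsonlite::write_json(manifest, pth("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(env = env, manifest = manifest))
}
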