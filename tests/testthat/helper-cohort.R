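## Default synthetic cohort processed through quantification and VST,
## built once and shared by the acceptance checks that exercise the
## study-scale conditions.
defaultCohortBundle <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        cfg <- cohortConfig(seed = 1)
        ann <- generateAnnotation(cfg)
        coh <- generateCohort(cfg, ann)
        ml <- suppressWarnings(maskedLengths(ann$geneModel))
        fp <- computeFpkm(coh$counts[ml$gene_id[ml$masked_length > 0], ],
                          ml)
        keep <- filterLowExpression(fp)
        sf <- estimateSizeFactors(coh$counts[keep, ])
        disp <- fitDispersions(coh$counts[keep, ], sf,
                               rep("all", cfg$nSamples))
        vst <- vstTransform(coh$counts[keep, ], sf, disp)
        lnc <- isLncRNA(ann$geneModel)
        cache <<- list(cfg = cfg, ann = ann, coh = coh, ml = ml,
                       fpkm = fp, keep = keep, sf = sf, vst = vst,
                       lncKeep = keep[lnc[keep]],
                       mrnaKeep = keep[!lnc[keep]])
        cache
    }
})
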