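#' @include AllClasses.R
NULL

#' Read a gene annotation from GTF into a GeneModel
#'
#' Parses exon features from a GTF file (GENCODE-dialect attributes
#' `gene_id`, `gene_type` or `gene_biotype`, optionally `gene_name`) and
#' builds one gene-level record per `gene_id`: exons are merged into a
#' non-overlapping union, and the TSS is the strand-aware 5' end of that
#' union (minimum start on `+`, maximum end on `-`). Genes whose biotype is
#' not `protein_coding` or one of the six lncRNA categories are skipped with
#' a warning; genes with exons on both strands are skipped likewise.
#'
#' @param path Path to a GTF file.
#' @return A [GeneModel-class] object.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste0('chr1\tx\texon\t101\t200\t.\t+\t.\t',
#'                   'gene_id "G1"; gene_name "G1"; ',
#'                   'gene_type "protein_coding";'), gtf)
#' gm <- readGeneAnnotation(gtf)
#' geneIds(gm)
#' @export
readGeneAnnotation <- function(path) {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0L)
        stop("no exon features found in ", path)
    if (is.null(gr$gene_id) || anyNA(gr$gene_id) || any(gr$gene_id == ""))
        stop("GTF parse error: exon feature without gene_id attribute ",
             "(first offending record index: ",
             if (is.null(gr$gene_id)) 1L else
                 which(is.na(gr$gene_id) | gr$gene_id == "")[1L], ")")
    bio <- gr$gene_type
    if (is.null(bio)) bio <- gr$gene_biotype
    if (is.null(bio))
        stop("GTF parse error: no gene_type/gene_biotype attribute")
    nm <- gr$gene_name
    if (is.null(nm)) nm <- gr$gene_id
    makeGeneModel(gr$gene_id, bio, nm, gr)
}

## assemble a GeneModel from per-exon vectors; shared by the GTF reader and
## the synthetic annotation generator
makeGeneModel <- function(gene_id, biotype, gene_name, exons) {
    keep <- biotype %in% .ALL_BIOTYPES
    if (!all(keep)) {
        bad <- unique(gene_id[!keep])
        warning("skipping ", length(bad),
                " gene(s) with unknown biotype: ",
                paste(utils::head(bad, 5L), collapse = ", "))
        sel <- !(gene_id %in% bad)
        gene_id <- gene_id[sel]; biotype <- biotype[sel]
        gene_name <- gene_name[sel]; exons <- exons[sel]
    }
    nstrand <- vapply(split(as.character(strand(exons)), gene_id),
                      function(s) length(unique(s)), 1L)
    if (any(nstrand > 1L)) {
        bad <- names(nstrand)[nstrand > 1L]
        warning("skipping ", length(bad), " gene(s) with exons on both ",
                "strands: ", paste(utils::head(bad, 5L), collapse = ", "))
        sel <- !(gene_id %in% bad)
        gene_id <- gene_id[sel]; biotype <- biotype[sel]
        gene_name <- gene_name[sel]; exons <- exons[sel]
    }
    ids <- unique(gene_id)
    grl <- reduce(GenomicRanges::split(GRanges(seqnames(exons),
                                               IRanges(start(exons),
                                                       end(exons)),
                                               strand = strand(exons)),
                                       factor(gene_id, levels = ids)))
    str <- vapply(split(as.character(strand(exons)), gene_id)[ids],
                  `[`, "", 1L)
    tss <- ifelse(str == "-", max(end(grl)), min(start(grl)))
    span <- range(grl)
    genes <- unlist(span, use.names = FALSE)
    mcols(genes) <- S4Vectors::DataFrame(
        gene_id = ids,
        gene_name = vapply(split(gene_name, gene_id)[ids], `[`, "", 1L),
        biotype = vapply(split(biotype, gene_id)[ids], `[`, "", 1L),
        tss = as.integer(tss))
    new("GeneModel", genes = genes, exons = grl)
}

#' Overlap-masked exonic gene lengths
#'
#' For every gene, computes the raw exonic length (total merged exon bases)
#' and the masked length: exonic bases not overlapped by any exonic base of
#' any gene of the *other* class (protein-coding vs lncRNA). The masking is
#' strand-blind, matching counting for a non-strand-specific library, and
#' mirrors union-mode counting: fragments in cross-class overlap regions are
#' discarded, so those bases are excluded from the effective length used for
#' FPKM.
#'
#' @param gm A [GeneModel-class].
#' @return A `data.frame` with columns `gene_id`, `raw_length`,
#'   `masked_length`. Genes with `masked_length == 0` are flagged with a
#'   warning (FPKM is undefined for them and they are dropped downstream).
#' @export
maskedLengths <- function(gm) {
    lnc <- isLncRNA(gm)
    exl <- exonsByGene(gm)
    lncUnion <- reduce(unlist(exl[lnc]), ignore.strand = TRUE)
    codUnion <- reduce(unlist(exl[!lnc]), ignore.strand = TRUE)
    raw <- sum(width(exl))
    ## overlap of each gene's exons with the other class's exon union;
    ## exons are merged per gene and the unions reduced, so pairwise
    ## intersection widths sum without double counting
    ex <- unlist(exl, use.names = FALSE)
    geneIdx <- rep(seq_along(exl), lengths(exl))
    overlapBases <- function(idx, union) {
        if (!length(idx) || !length(union)) return(numeric(0))
        hits <- findOverlaps(ex[idx], union, ignore.strand = TRUE)
        w <- width(IRanges::pintersect(
            IRanges::ranges(ex[idx][S4Vectors::queryHits(hits)]),
            IRanges::ranges(union[S4Vectors::subjectHits(hits)])))
        tapply(w, geneIdx[idx][S4Vectors::queryHits(hits)], sum)
    }
    masked <- raw
    ovL <- overlapBases(which(lnc[geneIdx]), codUnion)
    ovC <- overlapBases(which(!lnc[geneIdx]), lncUnion)
    for (ov in list(ovL, ovC)) {
        ix <- as.integer(names(ov))
        masked[ix] <- masked[ix] - ov
    }
    masked <- as.integer(masked)
    res <- data.frame(gene_id = geneIds(gm),
                      raw_length = as.integer(raw),
                      masked_length = masked,
                      stringsAsFactors = FALSE)
    zero <- res$gene_id[res$masked_length == 0L]
    if (length(zero))
        warning(length(zero), " gene(s) fully masked (length 0), ",
                "excluded from FPKM downstream: ",
                paste(utils::head(zero, 5L), collapse = ", "))
    res
}

#' Assign lncRNAs to neighboring coding genes (basal-plus-extension)
#'
#' Local re-implementation of the basal-plus-extension regulatory-domain
#' rule: every coding gene owns a basal domain from `basalUp` bases upstream
#' to `basalDown` bases downstream of its TSS (strand-aware), extended on
#' each side up to `maxExtension` bases from the TSS but stopping at the
#' basal domain of the nearest coding gene on that side. A lncRNA is
#' assigned to every coding gene whose regulatory domain contains the
#' lncRNA's TSS.
#'
#' The reported `distance` is signed relative to the lncRNA's strand:
#' negative when the coding TSS lies upstream of the lncRNA.
#'
#' @param gm A [GeneModel-class] containing both classes.
#' @param basalUp,basalDown Basal domain extent upstream/downstream of the
#'   coding TSS (bases).
#' @param maxExtension Maximum domain extent from the TSS (bases).
#' @return `data.frame` with columns `lnc_gene_id`, `coding_gene_id`,
#'   `distance` (signed TSS-to-TSS bases), `rule` (`"basal"` or
#'   `"extension"`).
#' @export
assignNeighbors <- function(gm, basalUp = 5000, basalDown = 1000,
                            maxExtension = 1e6) {
    lnc <- isLncRNA(gm)
    if (!any(lnc) || !any(!lnc))
        stop("need at least one lncRNA and one coding gene")
    g <- gm@genes
    cod <- g[!lnc]
    ln <- g[lnc]
    codChr <- as.character(seqnames(cod))
    lncChr <- as.character(seqnames(ln))
    only <- setdiff(union(codChr, lncChr), intersect(codChr, lncChr))
    if (length(only))
        message("chromosome(s) present in one class only, no assignments ",
                "there: ", paste(only, collapse = ", "))
    out <- list()
    for (chr in intersect(unique(codChr), unique(lncChr))) {
        ci <- which(codChr == chr)
        dom <- regulatoryDomains(cod$tss[ci],
                                 as.character(strand(cod))[ci],
                                 cod$gene_id[ci],
                                 basalUp, basalDown, maxExtension)
        li <- which(lncChr == chr)
        for (j in li) {
            t <- ln$tss[j]
            hit <- which(dom$domStart <= t & t <= dom$domEnd)
            if (!length(hit)) next
            inBasal <- dom$basStart[hit] <= t & t <= dom$basEnd[hit]
            s <- if (as.character(strand(ln))[j] == "-") -1L else 1L
            out[[length(out) + 1L]] <- data.frame(
                lnc_gene_id = ln$gene_id[j],
                coding_gene_id = dom$gene_id[hit],
                distance = s * (cod$tss[ci][hit] - t),
                rule = ifelse(inBasal, "basal", "extension"),
                stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(lnc_gene_id = character(), coding_gene_id =
                          character(), distance = integer(),
                          rule = character(), stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    res[order(res$lnc_gene_id, res$coding_gene_id), , drop = FALSE]
}

## basal-plus-extension domains for one chromosome; extension on each side
## runs to the nearest basal-domain edge among genes with a smaller (resp.
## larger) TSS, capped at maxExtension from the own TSS, and never shrinks
## the own basal domain
regulatoryDomains <- function(tss, strand, ids, basalUp, basalDown,
                              maxExtension) {
    minus <- strand == "-"
    basStart <- ifelse(minus, tss - basalDown, tss - basalUp)
    basEnd <- ifelse(minus, tss + basalUp, tss + basalDown)
    n <- length(tss)
    domStart <- numeric(n); domEnd <- numeric(n)
    ord <- order(tss, ids)
    for (i in seq_len(n)) {
        left <- which(tss < tss[i] | (tss == tss[i] & ids < ids[i]))
        right <- which(tss > tss[i] | (tss == tss[i] & ids > ids[i]))
        leftEdge <- if (length(left)) max(basEnd[left]) + 1 else -Inf
        rightEdge <- if (length(right)) min(basStart[right]) - 1 else Inf
        domStart[i] <- min(basStart[i], max(tss[i] - maxExtension, leftEdge))
        domEnd[i] <- max(basEnd[i], min(tss[i] + maxExtension, rightEdge))
    }
    data.frame(gene_id = ids, basStart = basStart, basEnd = basEnd,
               domStart = domStart, domEnd = domEnd,
               stringsAsFactors = FALSE)
}

#' Write a GeneModel back to GTF
#'
#' Emits one `exon` feature per merged exon with `gene_id`, `gene_name` and
#' `gene_type` attributes, so that [readGeneAnnotation()] round-trips.
#'
#' @param gm A [GeneModel-class].
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
writeGeneAnnotation <- function(gm, path) {
    exl <- exonsByGene(gm)
    n <- lengths(exl)
    ex <- unlist(exl, use.names = FALSE)
    mcols(ex) <- S4Vectors::DataFrame(
        source = "lncScape", type = "exon",
        gene_id = rep(geneIds(gm), n),
        gene_name = rep(gm@genes$gene_name, n),
        gene_type = rep(gm@genes$biotype, n))
    rtracklayer::export(ex, path, format = "gtf")
    invisible(path)
}
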