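#' @include AllClasses.R
NULL

#' Write / read a gene x sample matrix as TSV
#'
#' Plain TSV with a `gene_id` first column and one column per sample.
#'
#' @param mat Matrix with dimnames.
#' @param path Output path.
#' @return `path` (writer) or the matrix (reader), invisibly for the
#'   writer.
#' @export
writeMatrixTsv <- function(mat, path) {
    df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeMatrixTsv
#' @param integer Coerce values to integer (for count matrices).
#' @export
readMatrixTsv <- function(path, integer = FALSE) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1L]]
    if (integer) storage.mode(m) <- "integer"
    m
}

#' Write / read a generic TSV table
#'
#' @param df A data.frame.
#' @param path File path.
#' @return `path` invisibly (writer); a data.frame (reader).
#' @export
writeTableTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeTableTsv
#' @export
readTableTsv <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write gene sets to GMT
#'
#' One set per line: name, description, then member gene ids,
#' tab-separated (the format [readGmt()] reads).
#'
#' @param sets Named list of gene-id vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path) {
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}
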