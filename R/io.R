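#' Read and write expression matrices and sample tables as TSV
#'
#' The expression TSV has one row per gene with the gene identifier in the
#' first column (`gene_id`) and one column per sample. The sample TSV has one
#' row per sample with a `sample_id` column plus design factors.
#'
#' @param path file path.
#' @return `read_expression_tsv`: numeric genes x samples matrix with
#'   dimnames. `read_samples_tsv`: data.frame.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_expression_tsv
#' @param matrix numeric genes x samples matrix.
#' @export
write_expression_tsv <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_expression_tsv
#' @export
read_samples_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
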