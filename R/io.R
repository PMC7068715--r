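# Plain-text readers/writers for the pipeline's interchange formats.
# Everything is tab-separated with a header row; no binary caches.

#' Write a count matrix and its metadata as TSV
#' @param counts a \code{\link{count_matrix}}.
#' @param counts_path,metadata_path output files.
#' @return invisibly, the two paths.
#' @export
write_counts_tsv <- function(counts, counts_path, metadata_path) {
  df <- data.frame(gene_id = rownames(counts$counts), counts$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(counts$samples, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(counts_path, metadata_path))
}

#' Read a count matrix written by \code{\link{write_counts_tsv}}
#' @param counts_path,metadata_path input files.
#' @return a \code{\link{count_matrix}}.
#' @export
read_counts_tsv <- function(counts_path, metadata_path) {
  df <- read.delim(counts_path, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  samples <- read.delim(metadata_path, stringsAsFactors = FALSE)
  count_matrix(m, samples)
}

#' Write a numeric matrix with an id column as TSV
#' @param m matrix with rownames.
#' @param path output file.
#' @param id_name name of the id column.
#' @return the path, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_df_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
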