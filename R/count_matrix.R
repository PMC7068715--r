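#' Construct a count matrix container
#'
#' Couples a genes x samples matrix of non-negative integer counts with
#' its sample metadata, checking the two stay aligned.
#'
#' @param counts genes x samples matrix of non-negative integers with
#'   unique rownames (gene ids) and colnames (sample names).
#' @param samples data frame with columns sample, genotype, stage,
#'   replicate; rows must match the count columns.
#' @return object of class \code{count_matrix}.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample names")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  req <- c("sample", "genotype", "stage", "replicate")
  if (!all(req %in% names(samples)))
    stop("samples must have columns: ", paste(req, collapse = ", "))
  if (!identical(colnames(counts), samples$sample))
    stop("sample metadata does not align with count columns")
  structure(list(counts = counts, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

as_counts <- function(x) {
  if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
}
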