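#' Principal component analysis of sample expression
#'
#' SVD of the column-centered samples x genes matrix (samples are
#' observations, genes variables; no variable scaling by default).
#' Component signs are fixed by forcing each component's
#' largest-magnitude loading positive, so results are fully
#' deterministic.
#'
#' @param x samples x genes matrix.
#' @param center,scale passed to the decomposition (centering on by
#'   default, scaling off).
#' @return list of class \code{pca_result}: scores (samples x comps),
#'   loadings (genes x comps), eigenvalues (= sdev^2), variance_explained
#'   and cumulative fractions.
#' @export
pca_samples <- function(x, center = TRUE, scale = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need >= 2 samples and >= 2 genes")
  pr <- prcomp(x, center = center, scale. = scale)
  ev <- pr$sdev^2
  if (sum(ev) <= 0) stop("constant matrix: total variance is zero")
  for (j in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  structure(list(scores = pr$x, loadings = pr$rotation,
                 eigenvalues = ev,
                 variance_explained = ev / sum(ev),
                 cumulative = cumsum(ev) / sum(ev),
                 center = pr$center, scale = pr$scale),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ve <- round(100 * x$variance_explained[seq_len(min(3L, length(x$eigenvalues)))], 1)
  cat("pca_result: variance explained (%):", paste(ve, collapse = ", "),
      if (length(x$eigenvalues) > 3L) "..." else "", "\n")
  invisible(x)
}

#' Per-stage log2 fold-change matrix for heatmap display
#'
#' Extracts the fitted mutant-vs-WT log2 fold change at every stage for a
#' gene set (typically the genotype-dependent DEGs) and orders rows by
#' average-linkage hierarchical clustering on Euclidean distance. Missing
#' contrasts are imputed as 0 and flagged.
#'
#' @param deg a \code{deg_result} from \code{\link{classify_degs}} (or
#'   its \code{table}).
#' @param genes gene ids to include (rows).
#' @param stages stage order; defaults to the result's stages.
#' @return genes x stages numeric matrix, rows in display order;
#'   attribute \code{"n_imputed"} counts imputed entries.
#' @export
logfc_heatmap_matrix <- function(deg, genes, stages = NULL) {
  tab <- if (is.data.frame(deg)) deg else deg$table
  if (is.null(stages)) {
    stages <- if (!is.data.frame(deg)) deg$stages else
      sub("^logFC_", "", grep("^logFC_", names(tab), value = TRUE))
  }
  missing_genes <- setdiff(genes, tab$gene_id)
  if (length(missing_genes) > 0L)
    stop("genes absent from the DEG table: ",
         paste(utils::head(missing_genes, 5L), collapse = ", "))
  m <- as.matrix(tab[match(genes, tab$gene_id),
                     paste0("logFC_", stages), drop = FALSE])
  dimnames(m) <- list(genes, stages)
  n_imp <- sum(is.na(m))
  m[is.na(m)] <- 0
  if (nrow(m) > 2L) {
    ord <- hclust(dist(m), method = "average")$order
    m <- m[ord, , drop = FALSE]
  }
  attr(m, "n_imputed") <- n_imp
  m
}
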