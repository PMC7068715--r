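#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Between-sample scaling factors for count data, following the original
#' TMM recipe: the reference sample is the one whose upper-quartile CPM is
#' closest to the mean upper-quartile; each sample's factor is the
#' exponentiated precision-weighted mean of gene-wise log ratios (M)
#' against the reference after doubly trimming by M and by average log
#' abundance (A), genes with a zero in either sample excluded; factors are
#' rescaled to have geometric mean 1.
#'
#' @param counts a \code{\link{count_matrix}} or plain counts matrix.
#' @param trim_M two-sided trim fraction on M values.
#' @param trim_A two-sided trim fraction on A values.
#' @return data frame of class \code{library_stats}: sample, lib_size,
#'   tmm_factor, effective_lib_size.
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  y <- as_counts(counts)
  if (ncol(y) < 2L) stop("TMM needs at least 2 samples")
  lib <- colSums(y)
  if (any(lib == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(y)[lib == 0], collapse = ", "))

  # reference by the upper-quartile rule, ties to the lowest sample index
  uq <- apply(sweep(y, 2L, lib, "/"), 2L, quantile, probs = 0.75)
  ref_i <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(y)), function(i)
    tmm_pair(y[, i], y[, ref_i], lib[i], lib[ref_i], trim_M, trim_A),
    numeric(1L))
  f <- f / exp(mean(log(f)))
  out <- data.frame(sample = colnames(y), lib_size = unname(lib),
                    tmm_factor = f,
                    effective_lib_size = unname(lib) * f,
                    stringsAsFactors = FALSE)
  class(out) <- c("library_stats", class(out))
  attr(out, "reference_sample") <- colnames(y)[ref_i]
  out
}

# One sample against the reference: doubly-trimmed, precision-weighted
# mean of M values (rank-based trim bounds so ties are handled as in the
# published procedure).
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_M, trim_A) {
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; v <- v[fin]
  if (length(M) == 0L) return(1)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  f <- sum(M[keep] / v[keep]) / sum(1 / v[keep])
  if (!is.finite(f)) f <- 0
  2^f
}

#' Counts per million, optionally on the log2 scale
#'
#' CPM uses the effective library size (library size times TMM factor).
#' On the log scale a prior count is added, scaled by relative library
#' size so log-CPM stays comparable across depths:
#' \code{log2((count + pc_s) / (elib_s + 2 pc_s) * 1e6)} with
#' \code{pc_s = prior_count * elib_s / mean(elib)}.
#'
#' @param counts a \code{\link{count_matrix}} or matrix.
#' @param stats a \code{library_stats} from \code{\link{tmm_factors}};
#'   when NULL, factors of 1 are used.
#' @param log2 return log2-CPM.
#' @param prior_count pseudo-count for the log scale.
#' @return numeric genes x samples matrix.
#' @export
cpm_matrix <- function(counts, stats = NULL, log2 = FALSE, prior_count = 0.5) {
  y <- as_counts(counts)
  if (is.null(stats)) {
    elib <- colSums(y)
  } else {
    if (!all(colnames(y) %in% stats$sample))
      stop("library stats do not cover all samples")
    elib <- stats$effective_lib_size[match(colnames(y), stats$sample)]
  }
  if (!log2) return(sweep(y, 2L, elib, "/") * 1e6)
  pc <- prior_count * elib / mean(elib)
  log2(sweep(sweep(y, 2L, pc, "+"), 2L, elib + 2 * pc, "/") * 1e6)
}

#' Filter genes by total CPM across all samples
#'
#' Keeps genes whose CPM summed over every sample of both genotypes is
#' strictly greater than the threshold (a gene summing to exactly the
#' threshold is removed).
#'
#' @param cpm non-log CPM matrix.
#' @param threshold total-CPM cutoff.
#' @return character vector of retained gene ids.
#' @export
filter_total_cpm <- function(cpm, threshold = 10) {
  rownames(cpm)[rowSums(cpm) > threshold]
}

#' Pearson correlation matrix between samples
#'
#' @param logcpm genes x samples matrix (log2-CPM by convention).
#' @return samples x samples symmetric correlation matrix; pairs involving
#'   a zero-variance sample are NA.
#' @export
sample_correlation_matrix <- function(logcpm) {
  if (nrow(logcpm) < 2L) stop("need at least 2 genes")
  suppressWarnings(cc <- cor(logcpm))
  ok <- apply(logcpm, 2L, sd) > 0
  diag(cc)[ok] <- 1
  cc
}

#' Multidimensional scaling of samples by leading log-fold-change distance
#'
#' The distance between two samples is the root-mean-square of the
#' \code{top_genes} largest absolute log-fold-changes for that pair
#' (genes chosen per pair); the distance matrix is embedded by classical
#' metric scaling.
#'
#' @param logcpm genes x samples log-expression matrix.
#' @param top_genes number of top genes per pair.
#' @param dims embedding dimension (must be < number of samples).
#' @return list with \code{points} (samples x dims, centered) and
#'   \code{distance} (samples x samples matrix).
#' @export
mds_embedding <- function(logcpm, top_genes = 500L, dims = 2L) {
  n <- ncol(logcpm)
  if (n < 3L) stop("need at least 3 samples")
  if (dims >= n) stop("dims must be smaller than the number of samples")
  k <- min(top_genes, nrow(logcpm))
  d <- matrix(0, n, n, dimnames = list(colnames(logcpm), colnames(logcpm)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      lfc <- logcpm[, i] - logcpm[, j]
      top <- sort(lfc^2, decreasing = TRUE)[seq_len(k)]
      d[i, j] <- d[j, i] <- sqrt(mean(top))
    }
  }
  pts <- cmdscale(d, k = dims)
  pts <- sweep(pts, 2L, colMeans(pts))
  colnames(pts) <- paste0("dim", seq_len(dims))
  list(points = pts, distance = d)
}
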