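# Independent brute-force oracles and small fixture builders.
# Oracles deliberately re-derive each quantity from its definition, step
# by step, without calling the package's implementation path.

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- (n / seq_len(n)) * p[o]
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(1, q_sorted)
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# Absolute-tolerance comparison (expect_equal's tolerance is relative,
# which is too strict for values near zero).
expect_near <- function(actual, expected, tol) {
  testthat::expect_lt(max(abs(actual - expected)), tol)
}

# Exact hypergeometric upper tail by summing binomial-coefficient ratios.
oracle_hyper_tail <- function(N, K, n, k) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# TMM recomputed from its definition: reference by upper-quartile rule,
# M/A/weights explicit, rank-based double trim, precision-weighted mean.
oracle_tmm <- function(counts, trim_M = 0.3, trim_A = 0.05) {
  lib <- colSums(counts)
  uq <- vapply(seq_len(ncol(counts)),
               function(i) unname(quantile(counts[, i] / lib[i], 0.75)),
               numeric(1))
  ref <- which.min(abs(uq - mean(uq)))
  fac <- vapply(seq_len(ncol(counts)), function(i) {
    o <- counts[, i]; r <- counts[, ref]
    keep <- o > 0 & r > 0
    o <- o[keep]; r <- r[keep]
    M <- log2((o / lib[i]) / (r / lib[ref]))
    A <- 0.5 * log2((o / lib[i]) * (r / lib[ref]))
    if (length(M) == 0 || max(abs(M)) < 1e-6) return(1)
    v <- (lib[i] - o) / (lib[i] * o) + (lib[ref] - r) / (lib[ref] * r)
    n <- length(M)
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    k <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[k] / v[k]) / sum(1 / v[k]))
  }, numeric(1))
  fac / exp(mean(log(fac)))
}

oracle_nearest_prototype <- function(prototypes, x) {
  t(apply(x, 1, function(v) {
    d <- sqrt(colSums((t(prototypes) - v)^2))
    i <- unname(which.min(d))  # which.min takes the first of ties
    c(unit = i, distance = unname(d[i]))
  }))
}

# Area under the precision-recall curve by step integration over recall.
pr_auc <- function(score, truth) {
  ok <- !is.na(score)
  score <- score[ok]; truth <- truth[ok]
  o <- order(score, decreasing = TRUE)
  t <- truth[o]
  tp <- cumsum(t); fp <- cumsum(!t)
  prec <- tp / (tp + fp)
  rec <- tp / sum(t)
  sum(diff(c(0, rec)) * prec)
}

# Small random count fixture with metadata, genes x samples.
random_count_fixture <- function(n_genes = 60, n_samples = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = 50, size = 5),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%d", seq_len(n_samples))))
  m
}

# Simulated study with defaults scaled to test size.
small_study <- function(n_genes, seed, replicates = 3, ...) {
  d <- study_design(replicates_per_cell = replicates, n_genes = n_genes)
  pr <- generate_programs(d, n_genes, seed = seed, ...)
  cm <- simulate_counts(pr, d, seed = seed + 1L)
  list(design = d, programs = pr, truth = truth_table(pr), counts = cm)
}
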