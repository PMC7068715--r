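test_that("program generation handles degenerate input, seeds and quotas", {
  d <- study_design()
  expect_equal(nrow(generate_programs(d, 0)), 0L)
  expect_equal(nrow(truth_table(generate_programs(d, 0))), 0L)

  p1 <- generate_programs(d, 1000, frac_delayed = 0.3, seed = 7)
  p2 <- generate_programs(d, 1000, frac_delayed = 0.3, seed = 7)
  expect_identical(truth_table(p1), truth_table(p2))

  # deterministic quota assignment
  p <- generate_programs(d, 10000, frac_delayed = 0.3, seed = 3)
  expect_equal(sum(p$delayed_in_mut), 3000L)
  expect_equal(sum(p$is_null), round(10000 * 0.2))

  expect_error(generate_programs(d, 100, frac_delayed = -0.1), "fractions")
  expect_error(generate_programs(d, 100, frac_delayed = 0.8, frac_null = 0.5),
               "exceed")

  # null genes are flat and unshifted
  expect_true(all(p$amplitude[p$is_null] == 0))
  expect_true(all(p$genotype_shift[p$is_null] == 0))
  expect_true(all(p$archetype[p$is_null] == "flat"))
})

test_that("archetype profiles are zero-mean unit-variance except flat", {
  a <- archetype_profiles(5)
  expect_equal(nrow(a), 8L)
  nonflat <- a[rownames(a) != "flat", ]
  expect_equal(unname(rowMeans(nonflat)), rep(0, nrow(nonflat)))
  expect_equal(unname(apply(nonflat, 1, sd)), rep(1, nrow(nonflat)))
  expect_equal(unname(a["flat", ]), rep(0, 5))
})

test_that("count matrices match the design and are reproducible", {
  s <- small_study(150, seed = 5)
  expect_equal(dim(s$counts$counts), c(150L, 30L))
  expect_true(all(s$counts$counts >= 0))
  expect_identical(colnames(s$counts$counts), s$design$samples$sample)
  c2 <- simulate_counts(s$programs, s$design, seed = 6)
  expect_identical(s$counts$counts, c2$counts)
  expect_error(simulate_counts(s$programs[0, ], s$design), "non-empty")
})

test_that("zero dispersion and fixed depth give Poisson-like counts", {
  # flat genes, fixed depth, 200 replicates/cell: index of dispersion -> 1
  d <- study_design(genotypes = "WT", replicates_per_cell = 200,
                    n_genes = 100)
  pr <- generate_programs(d, 100, frac_delayed = 0, frac_null = 1, seed = 2)
  pr$dispersion[] <- 0
  cm <- simulate_counts(pr, d, libsize_log_sd = 0, seed = 3)
  iod <- apply(cm$counts, 1, var) / rowMeans(cm$counts)
  expect_gt(mean(iod), 0.9)
  expect_lt(mean(iod), 1.1)
})

test_that("a profile doubling across stages doubles the simulated means", {
  # one doubling gene diluted in 500 flat genes so the library
  # composition stays essentially constant across stages
  d <- study_design(genotypes = "WT", replicates_per_cell = 1000,
                    n_genes = 501)
  pr <- generate_programs(d, 501, frac_delayed = 0, frac_null = 1, seed = 4)
  a <- archetype_profiles(5)
  # monotone-up gene with amplitude chosen for exactly 1 log2 unit of swing
  pr$archetype[1] <- "up"
  pr$amplitude[1] <- 1 / (a["up", 5] - a["up", 1])
  pr$is_null[1] <- FALSE
  pr$base_mean[1] <- 50
  pr$dispersion[] <- 0
  cm <- simulate_counts(pr, d, libsize_log_sd = 0, seed = 5)

  # closed-form means including the compositional normalization
  ex <- expected_log2_expression(pr, d)
  q <- 2^ex$WT
  mu <- 5e6 * q[1, ] / colSums(q)
  expect_equal(unname(mu["ST11"] / mu["ST8"]), 2, tolerance = 0.01)

  st8 <- cm$samples$sample[cm$samples$stage == "ST8"]
  st11 <- cm$samples$sample[cm$samples$stage == "ST11"]
  m8 <- mean(cm$counts[1, st8]); m11 <- mean(cm$counts[1, st11])
  se <- sqrt(var(cm$counts[1, st11]) / 1000 +
               4 * var(cm$counts[1, st8]) / 1000)
  expect_lt(abs(m11 - 2 * m8), 3 * se + 0.01 * m11)
})

test_that("delayed genes express the WT program one stage later", {
  d <- study_design(n_genes = 50)
  pr <- generate_programs(d, 50, frac_delayed = 1, frac_null = 0, seed = 6)
  pr$genotype_shift[] <- 0
  ex <- expected_log2_expression(pr, d)
  shifted <- t(apply(ex$WT, 1, function(v) c(v[1], v[-5])))
  expect_equal(unname(ex$MUT), unname(shifted))

  # cross-correlation of noise-free stage means peaks at lag +1 for
  # delayed genes and lag 0 otherwise; the check is restricted to
  # transient interior peaks -- a monotone profile correlates perfectly
  # with its own lagged copy and a boundary spike shifts off the stage
  # window, so lag is ill-defined for those shapes
  pr2 <- generate_programs(d, 50, frac_delayed = 0.5, frac_null = 0, seed = 8)
  pr2$genotype_shift[] <- 0
  ex2 <- expected_log2_expression(pr2, d)
  best_lag <- vapply(seq_len(50), function(g) {
    wt <- ex2$WT[g, ]; mut <- ex2$MUT[g, ]
    lags <- 0:2
    cors <- vapply(lags, function(L) {
      a <- wt[seq_len(5 - L)]; b <- mut[seq_len(5 - L) + L]
      if (sd(a) == 0 || sd(b) == 0) return(-Inf)
      cor(a, b)
    }, numeric(1))
    lags[which.max(cors)]
  }, numeric(1))
  transient <- pr2$archetype %in% c("peak2", "peak3", "peak4")
  expect_true(any(transient & pr2$delayed_in_mut))
  expect_true(all(best_lag[transient & pr2$delayed_in_mut] == 1))
  expect_true(all(best_lag[transient & !pr2$delayed_in_mut] == 0))
})

test_that("annotation generation controls delayed-gene enrichment", {
  d <- study_design(n_genes = 2000)
  pr <- generate_programs(d, 2000, frac_delayed = 0.1, frac_null = 0.2, seed = 9)
  tr <- truth_table(pr)

  a0 <- generate_annotation(tr, n_terms = 200, genes_per_term = 20,
                            frac_terms_enriched_in_delayed = 0, seed = 10)
  frac0 <- mean(tapply(a0$gene_id %in% tr$gene_id[tr$delayed_in_mut],
                       a0$term_id, mean))
  expect_lt(abs(frac0 - 0.1), 0.02)

  # odds-ratio-5 enriched terms: expected delayed fraction from the
  # weighted-sampling construction, 200 delayed of 2000 genes
  tr2 <- tr; tr2$delayed_in_mut <- seq_len(2000) <= 200
  a5 <- generate_annotation(tr2, n_terms = 200, genes_per_term = 20,
                            frac_terms_enriched_in_delayed = 1,
                            odds_ratio = 5, seed = 11)
  is_del <- a5$gene_id %in% tr2$gene_id[tr2$delayed_in_mut]
  p_expect <- 5 * 200 / (5 * 200 + 1800)
  n_draws <- nrow(a5)
  expect_lt(abs(mean(is_del) - p_expect),
            4 * sqrt(p_expect * (1 - p_expect) / n_draws) + 0.01)

  expect_identical(generate_annotation(tr, 10, 20, seed = 12),
                   generate_annotation(tr, 10, 20, seed = 12))
  expect_error(generate_annotation(tr, 10, genes_per_term = 5000), "exceeds")
})

test_that("synthetic Ct tables encode expression as cycle differences", {
  d <- study_design(n_genes = 20)
  pr <- generate_programs(d, 20, frac_delayed = 0, frac_null = 0, seed = 13)
  ct <- generate_ct_table(pr, d, genes = pr$gene_id[1], noise_sd = 0)
  ref <- ct[ct$gene == "OsUbiquitin5", ]
  tgt <- ct[ct$gene == pr$gene_id[1], ]
  dct <- tgt$ct - ref$ct[match(tgt$sample, ref$sample)]
  ex <- expected_log2_expression(pr, d)
  lvl <- vapply(seq_len(nrow(tgt)), function(i)
    ex[[tgt$genotype[i]]][pr$gene_id[1], tgt$stage[i]], numeric(1))
  expect_equal(dct, -lvl, tolerance = 1e-12)
  expect_error(generate_ct_table(pr, d, efficiency = 1), "efficiency")
  expect_error(generate_ct_table(pr, d, noise_sd = -1), "noise_sd")
})
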