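make_gene <- function(n = 6, mu = 40, seed = 1) {
  set.seed(seed)
  y <- matrix(rnbinom(n, mu = mu, size = 5), 1,
              dimnames = list("g", paste0("s", seq_len(n))))
  y
}

test_that("NB GLM closed forms hold for intercept and group-means models", {
  y <- make_gene(6, seed = 1)
  off <- log(runif(6, 0.8e6, 1.2e6))
  # Poisson intercept-only MLE: sum(y) / sum(exp(offset))
  f <- fit_nb_glm(y, matrix(1, 6, 1), off, 0)
  expect_equal(unname(exp(f$coefficients[1, 1])),
               sum(y) / sum(exp(off)), tolerance = 1e-8)

  # group-means model with equal offsets: fitted means = group means,
  # for any dispersion
  X <- cbind(gA = rep(c(1, 0), each = 3), gB = rep(c(0, 1), each = 3))
  off0 <- rep(log(1e6), 6)
  f2 <- fit_nb_glm(y, X, off0, 0.2)
  expect_equal(unname(f2$fitted[1, 1:3]), rep(mean(y[1, 1:3]), 3),
               tolerance = 1e-6)
  expect_equal(unname(f2$fitted[1, 4:6]), rep(mean(y[1, 4:6]), 3),
               tolerance = 1e-6)
})

test_that("IRLS deviance matches brute-force likelihood maximization", {
  nb_negll <- function(beta, y, X, off, phi) {
    mu <- exp(X %*% beta + off)
    r <- 1 / phi
    -sum(lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
           y * log(mu / (mu + r)) + r * log(r / (mu + r)))
  }
  nb_dev <- function(y, mu, phi) {
    r <- 1 / phi
    term <- ifelse(y > 0, y * log(y / mu), 0)
    2 * sum(term - (y + r) * log((y + r) / (mu + r)))
  }
  for (seed in 1:5) {
    y <- make_gene(6, mu = 60, seed = seed)
    set.seed(seed + 50)
    X <- cbind(1, rnorm(6))
    off <- rnorm(6, log(1e5), 0.1)
    f <- fit_nb_glm(y, X, off, 0.2)
    o <- optim(c(0, 0), nb_negll, y = y[1, ], X = X, off = off, phi = 0.2,
               method = "BFGS", control = list(reltol = 1e-14))
    mu_o <- exp(X %*% o$par + off)
    expect_equal(unname(f$deviance), nb_dev(y[1, ], mu_o[, 1], 0.2),
                 tolerance = 1e-4)
  }
})

test_that("zero dispersion reproduces reference Poisson regression", {
  worst <- 0
  for (seed in 1:50) {
    set.seed(seed)
    n <- 6
    y <- matrix(rpois(n, runif(1, 5, 80)), 1,
                dimnames = list("g", paste0("s", 1:n)))
    X <- cbind(1, rnorm(n))
    off <- rnorm(n, 0, 0.2)
    f <- fit_nb_glm(y, X, off, 0)
    g <- glm(y[1, ] ~ X[, 2] + offset(off), family = poisson())
    worst <- max(worst, max(abs(f$coefficients[1, ] - coef(g))))
  }
  expect_lt(worst, 1e-6)
})

test_that("all-zero genes stay finite via the fitted-mean floor", {
  y <- matrix(0L, 1, 6, dimnames = list("g", paste0("s", 1:6)))
  f <- fit_nb_glm(y, matrix(1, 6, 1), rep(log(1e6), 6), 0.1)
  expect_true(all(is.finite(f$fitted)))
  expect_true(all(f$fitted > 0))
})

test_that("dispersion estimation recovers truth and shrinks degenerately", {
  set.seed(21)
  G <- 2000; n <- 6
  X <- stats::model.matrix(~ factor(rep(c("A", "B"), each = 3)))
  mu <- exp(rnorm(G, log(100), 1))
  off <- rep(0, n)

  # Poisson data: common estimate near zero
  yp <- matrix(rpois(G * n, rep(mu, n)), G, n,
               dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
  dp <- estimate_dispersions(yp, X, off)
  expect_lte(dp$common, 0.05)

  # NB data at phi = 0.4: recovery within [0.3, 0.5]
  yn <- matrix(rnbinom(G * n, mu = rep(mu, n), size = 1 / 0.4), G, n,
               dimnames = dimnames(yp))
  dn <- estimate_dispersions(yn, X, off)
  expect_gte(dn$common, 0.3)
  expect_lte(dn$common, 0.5)

  # single gene: tagwise shrinks onto the only anchor, the common value
  d1 <- estimate_dispersions(yn[1, , drop = FALSE], X, off)
  expect_equal(unname(d1$tagwise), d1$common, tolerance = 1e-12)

  expect_error(estimate_dispersions(yn / 2, X, off), "integers")
})

test_that("the LRT is calibrated, powered and order-invariant", {
  set.seed(31)
  G <- 2000; n <- 6
  X <- stats::model.matrix(~ factor(rep(c("A", "B"), each = 3)))
  X0 <- matrix(1, n, 1)
  off <- rep(0, n)
  mu <- exp(rnorm(G, log(100), 1))
  y <- matrix(rnbinom(G * n, mu = rep(mu, n), size = 1 / 0.1), G, n,
              dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
  dsp <- estimate_dispersions(y, X, off)
  full <- fit_nb_glm(y, X, off, dsp$tagwise)
  red <- fit_nb_glm(y, X0, off, dsp$tagwise)
  lr <- lrt(full, red)
  # identical designs: statistic 0, p 1
  same <- lrt(full, full)
  expect_equal(same$statistic, rep(0, G))
  expect_equal(same$p, rep(1, G))
  # null calibration at alpha = 0.05
  expect_gte(mean(lr$p < 0.05), 0.035)
  expect_lte(mean(lr$p < 0.05), 0.065)

  # power: constructed 8-fold effect, 3 vs 3
  set.seed(32)
  Gp <- 200
  mu2 <- exp(rnorm(Gp, log(100), 0.5))
  yA <- matrix(rnbinom(Gp * 3, mu = rep(mu2, 3), size = 10), Gp, 3)
  yB <- matrix(rnbinom(Gp * 3, mu = rep(8 * mu2, 3), size = 10), Gp, 3)
  yp <- cbind(yA, yB)
  dimnames(yp) <- list(paste0("g", 1:Gp), paste0("s", 1:6))
  dspp <- estimate_dispersions(yp, X, off)
  fullp <- fit_nb_glm(yp, X, off, dspp$tagwise)
  redp <- fit_nb_glm(yp, X0, off, dspp$tagwise)
  expect_gte(mean(lrt(fullp, redp)$p < 1e-3), 0.9)

  # sample reordering leaves the statistics unchanged
  perm <- c(4, 1, 6, 3, 2, 5)
  full2 <- fit_nb_glm(yp[, perm], X[perm, ], off[perm], dspp$tagwise)
  red2 <- fit_nb_glm(yp[, perm], X0[perm, , drop = FALSE], off[perm],
                     dspp$tagwise)
  expect_equal(lrt(full2, red2)$statistic, lrt(fullp, redp)$statistic,
               tolerance = 1e-6)
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_fdr(rep(1, 10)), rep(1, 10))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(41)
  p <- runif(5000)
  expect_equal(bh_fdr(p), oracle_bh(p))
  p[10] <- NA
  q <- bh_fdr(p)
  expect_true(is.na(q[10]))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("DEG classification controls false positives and finds structure", {
  # pure null simulation: ASD fraction bounded
  d <- study_design(n_genes = 2000)
  pr <- generate_programs(d, 2000, frac_delayed = 0, frac_null = 1, seed = 51)
  cm <- simulate_counts(pr, d, seed = 52)
  deg <- classify_degs(cm, tmm_factors(cm), stages = d$stages,
                       genotypes = d$genotypes)
  expect_lte(deg$summary$n_asd / deg$summary$n_tested, 2 * 0.01)

  # a gene identical across genotypes is not genotype-dependent
  s <- small_study(400, seed = 53, frac_delayed = 0, frac_shifted = 0,
                   frac_null = 0.5)
  deg2 <- classify_degs(s$counts, tmm_factors(s$counts),
                        stages = s$design$stages,
                        genotypes = s$design$genotypes)
  expect_lt(mean(deg2$table$is_ADD), 0.2)
  upcols <- paste0("up_", s$design$stages)
  downcols <- paste0("down_", s$design$stages)
  flat_add_rate <- mean(deg2$table$is_ADD)
  expect_lt(flat_add_rate, 0.2)

  # delayed genes are recovered as genotype-dependent with the up/down
  # peak at the built-in separation stage
  s3 <- small_study(1500, seed = 55)
  deg3 <- classify_degs(s3$counts, tmm_factors(s3$counts),
                        stages = s3$design$stages,
                        genotypes = s3$design$genotypes)
  m <- merge(deg3$table[, c("gene_id", "is_ADD")], s3$truth)
  expect_gte(mean(m$is_ADD[m$delayed_in_mut]), 0.7)
  tot <- deg3$summary$up_by_stage + deg3$summary$down_by_stage
  expect_identical(names(which.max(tot)),
                   max_separation_stage(s3$programs, s3$design))
  # up and down are mutually exclusive per gene-stage
  up <- as.matrix(deg3$table[, paste0("up_", s3$design$stages)])
  down <- as.matrix(deg3$table[, paste0("down_", s3$design$stages)])
  expect_false(any(up & down, na.rm = TRUE))
})
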