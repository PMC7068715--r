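#' Fit negative-binomial GLMs gene-wise
#'
#' Log-link NB regression solved by Fisher-scoring IRLS, one fit per gene
#' with a shared design matrix and per-sample offsets (log effective
#' library sizes). With dispersion 0 the model reduces exactly to Poisson
#' regression. Convergence is declared when the relative deviance change
#' falls below \code{tol} (default 1e-8) within \code{maxit} iterations;
#' non-convergence is flagged, not fatal, and fitted means are floored at
#' 1e-8 so all-zero genes stay finite.
#'
#' @param counts genes x samples matrix (or \code{count_matrix}).
#' @param design samples x coefficients design matrix (full column rank).
#' @param offset per-sample log effective library sizes.
#' @param dispersion per-gene NB dispersion phi (scalar recycled).
#' @param maxit,tol IRLS controls.
#' @return list of class \code{nb_fit}: coefficients (genes x p, natural
#'   log scale), deviance, fitted (genes x samples), converged, plus the
#'   design and dispersion used.
#' @export
fit_nb_glm <- function(counts, design, offset, dispersion,
                       maxit = 50L, tol = 1e-8) {
  y <- as_counts(counts)
  design <- as.matrix(design)
  if (nrow(design) != ncol(y)) stop("design rows must match samples")
  if (qr(design)$rank < ncol(design)) stop("design matrix is rank-deficient")
  if (!all(is.finite(offset)) || length(offset) != ncol(y))
    stop("offset must be finite, one value per sample")
  if (any(dispersion < 0)) stop("dispersion must be >= 0")
  phi <- rep_len(dispersion, nrow(y))
  fit <- .nb_glm_fit_cpp(y, design, offset, phi, maxit, tol)
  dimnames(fit$coefficients) <- list(rownames(y), colnames(design))
  dimnames(fit$fitted) <- dimnames(y)
  fit$deviance <- as.numeric(fit$deviance)
  names(fit$deviance) <- rownames(y)
  fit$design <- design
  fit$offset <- offset
  fit$dispersion <- phi
  class(fit) <- "nb_fit"
  fit
}

#' Estimate common and tagwise NB dispersions
#'
#' The common dispersion maximizes the Cox-Reid adjusted profile
#' likelihood (APL) pooled over genes, searched on a log grid over
#' \code{[1e-6, 10]} with local quadratic interpolation. Tagwise values
#' maximize each gene's APL after weighted-likelihood shrinkage toward
#' the pooled average with prior weight \code{prior_df / residual df}
#' (prior_df defaults to 10, stabilizing three-replicate designs). With a
#' single gene the shrunk objective is proportional to the pooled one, so
#' tagwise equals common exactly.
#'
#' @param counts genes x samples matrix or \code{count_matrix}.
#' @param design design matrix used for the Cox-Reid adjustment.
#' @param offset per-sample log effective library sizes.
#' @param prior_df prior degrees of freedom for shrinkage.
#' @param grid_length number of grid points on log-phi.
#' @return list: common (scalar), tagwise (per-gene vector), grid, apl.
#' @export
estimate_dispersions <- function(counts, design, offset,
                                 prior_df = 10, grid_length = 61L) {
  y <- as_counts(counts)
  if (any(y != round(y))) stop("counts must be integers")
  design <- as.matrix(design)
  if (ncol(y) <= ncol(design))
    stop("need more samples than coefficients")
  grid <- exp(seq(log(1e-6), log(10), length.out = grid_length))
  apl <- .nb_apl_cpp(y, design, offset, grid, 50L, 1e-8)

  common <- grid_argmax(colSums(apl), grid)
  df_resid <- ncol(y) - ncol(design)
  prior_n <- prior_df / df_resid
  shrunk <- apl + prior_n * matrix(colMeans(apl), nrow(y), length(grid),
                                   byrow = TRUE)
  tagwise <- vapply(seq_len(nrow(y)), function(g)
    grid_argmax(shrunk[g, ], grid), numeric(1L))
  names(tagwise) <- rownames(y)
  list(common = common, tagwise = tagwise, grid = grid, apl = apl)
}

# Maximize a curve sampled on a positive grid: take the best grid point
# and refine by quadratic interpolation in log-phi (clamped to the grid
# range at the boundaries).
grid_argmax <- function(vals, grid) {
  i <- which.max(vals)
  if (i == 1L || i == length(grid)) return(grid[i])
  lx <- log(grid[(i - 1L):(i + 1L)])
  vy <- vals[(i - 1L):(i + 1L)]
  denom <- (vy[1L] - 2 * vy[2L] + vy[3L])
  if (denom >= 0) return(grid[i])
  xstar <- lx[2L] - 0.5 * (lx[3L] - lx[1L]) / 2 * (vy[3L] - vy[1L]) / denom
  exp(min(max(xstar, lx[1L]), lx[3L]))
}

#' Likelihood-ratio test between nested NB GLM fits
#'
#' Statistic = reduced deviance - full deviance, referred to a chi-square
#' with df equal to the difference in coefficient counts. The same
#' dispersions must be used in both fits. Small negative statistics
#' (above -1e-6) are clamped to 0; larger negatives indicate a
#' convergence failure and are returned as NA with a warning.
#'
#' @param full,reduced \code{nb_fit} objects with nested designs.
#' @return data frame: gene_id, statistic, df, p.
#' @export
lrt <- function(full, reduced) {
  if (ncol(reduced$design) > ncol(full$design))
    stop("reduced design must be nested in the full design")
  if (!isTRUE(all.equal(full$dispersion, reduced$dispersion)))
    stop("full and reduced fits must share dispersions")
  stat <- reduced$deviance - full$deviance
  bad <- stat < -1e-6
  if (any(bad)) {
    warning(sum(bad), " gene(s) with negative LRT statistic beyond -1e-6; ",
            "returned as NA (convergence failure)")
    stat[bad] <- NA_real_
  }
  stat <- pmax(stat, 0)
  df <- ncol(full$design) - ncol(reduced$design)
  p <- if (df == 0L) rep(1, length(stat)) else pchisq(stat, df, lower.tail = FALSE)
  p[is.na(stat)] <- NA_real_
  data.frame(gene_id = names(full$deviance), statistic = unname(stat),
             df = df, p = unname(p), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; NA p-values
#' propagate as NA q-values.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# Design matrices for the stage/genotype factor models. The one-way
# "group" parameterization carries one coefficient per genotype x stage
# cell; the single-factor models use treatment contrasts.
design_matrices <- function(samples, stages, genotypes) {
  stage <- factor(samples$stage, levels = stages)
  geno <- factor(samples$genotype, levels = genotypes)
  group <- factor(paste(geno, stage, sep = "."),
                  levels = as.vector(t(outer(genotypes, stages, paste, sep = "."))))
  list(
    group = stats::model.matrix(~ 0 + group),
    additive = stats::model.matrix(~ geno + stage),
    stage_only = stats::model.matrix(~ stage),
    geno_only = stats::model.matrix(~ geno),
    intercept = stats::model.matrix(~ 1, data = samples),
    group_levels = levels(group)
  )
}

#' Classify stage- and genotype-dependent differentially expressed genes
#'
#' Defines the two DEG classes of the analysis. A gene is an ASD
#' (anther/stage-dependent DEG) when its BH FDR falls below
#' \code{alpha_asd} in the LRT of the genotype+stage model against the
#' intercept-only model, or (default "union" mode) in either single-factor
#' LRT (stage vs intercept, genotype vs intercept). A gene is an ADD
#' (autophagy/genotype-dependent DEG) when any per-stage mutant-vs-WT
#' contrast -- taken from a one-way genotype x stage parameterization --
#' reaches BH FDR below \code{alpha_add}. Per-stage up/down flags require
#' additionally |log2FC| >= \code{lfc_threshold} (fitted fold changes,
#' from coefficient differences). Genes with all-zero counts are excluded
#' before testing.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param stats \code{library_stats} from \code{\link{tmm_factors}}
#'   (NULL for factors of 1).
#' @param stages,genotypes factor level orders; defaults taken from the
#'   metadata in study order. The first genotype is the reference (WT).
#' @param alpha_asd,alpha_add FDR thresholds for the two classes.
#' @param lfc_threshold absolute log2FC needed for the up/down flags.
#' @param asd_mode "union" (either single-factor test) or "joint"
#'   (genotype+stage vs intercept only).
#' @param dispersion optional list from \code{\link{estimate_dispersions}};
#'   computed from the one-way design when NULL.
#' @param prior_df shrinkage prior df when dispersions are estimated here.
#' @return list of class \code{deg_result}: \code{table} (per-gene logFC,
#'   p, q, flags), \code{summary} (ASD/ADD totals and per-stage up/down
#'   counts), \code{dispersion}, \code{n_excluded}.
#' @export
classify_degs <- function(counts, stats = NULL,
                          stages = NULL, genotypes = NULL,
                          alpha_asd = 0.01, alpha_add = 0.05,
                          lfc_threshold = 1,
                          asd_mode = c("union", "joint"),
                          dispersion = NULL, prior_df = 10) {
  asd_mode <- match.arg(asd_mode)
  y <- as_counts(counts)
  samples <- counts$samples
  if (is.null(stages)) stages <- unique(samples$stage)
  if (is.null(genotypes)) genotypes <- unique(samples$genotype)

  cell_n <- table(samples$genotype, samples$stage)
  missing_cells <- cell_n[cell_n == 0]
  if (any(cell_n < 2))
    warning("genotype x stage cells with < 2 replicates; contrasts there are unstable")

  keep <- rowSums(y) > 0
  n_excluded <- sum(!keep)
  y <- y[keep, , drop = FALSE]

  if (is.null(stats)) {
    elib <- colSums(y)
  } else {
    elib <- stats$effective_lib_size[match(colnames(y), stats$sample)]
  }
  offset <- log(elib)
  dm <- design_matrices(samples, stages, genotypes)

  if (is.null(dispersion))
    dispersion <- estimate_dispersions(y, dm$group, offset, prior_df = prior_df)
  phi <- dispersion$tagwise

  fit_group <- fit_nb_glm(y, dm$group, offset, phi)
  fit_add <- fit_nb_glm(y, dm$additive, offset, phi)
  fit_stage <- fit_nb_glm(y, dm$stage_only, offset, phi)
  fit_geno <- fit_nb_glm(y, dm$geno_only, offset, phi)
  fit_int <- fit_nb_glm(y, dm$intercept, offset, phi)

  lrt_joint <- lrt(fit_add, fit_int)
  lrt_stage <- lrt(fit_stage, fit_int)
  lrt_geno <- lrt(fit_geno, fit_int)

  tab <- data.frame(gene_id = rownames(y), stringsAsFactors = FALSE)
  tab$p_joint <- lrt_joint$p;  tab$q_joint <- bh_fdr(tab$p_joint)
  tab$p_stage <- lrt_stage$p;  tab$q_stage <- bh_fdr(tab$p_stage)
  tab$p_geno <- lrt_geno$p;    tab$q_geno <- bh_fdr(tab$p_geno)
  tab$is_ASD <- if (asd_mode == "union") {
    tab$q_stage < alpha_asd | tab$q_geno < alpha_asd
  } else {
    tab$q_joint < alpha_asd
  }

  # per-stage genotype contrasts: drop the two cell coefficients for the
  # stage and replace them with a merged column (reduced, nested model)
  ref <- genotypes[1L]; mut <- genotypes[2L]
  up <- down <- matrix(FALSE, nrow(y), length(stages))
  lfc <- qmat <- pmat <- matrix(NA_real_, nrow(y), length(stages))
  colnames(lfc) <- colnames(pmat) <- colnames(qmat) <-
    colnames(up) <- colnames(down) <- stages
  for (si in seq_along(stages)) {
    st <- stages[si]
    if (cell_n[ref, st] == 0 || cell_n[mut, st] == 0) {
      warning("stage ", st, " missing a genotype; contrast skipped")
      next
    }
    iw <- match(paste(ref, st, sep = "."), dm$group_levels)
    im <- match(paste(mut, st, sep = "."), dm$group_levels)
    lfc[, si] <- (fit_group$coefficients[, im] -
                  fit_group$coefficients[, iw]) / log(2)
    red <- dm$group[, -c(iw, im), drop = FALSE]
    red <- cbind(red, merged = dm$group[, iw] + dm$group[, im])
    fit_red <- fit_nb_glm(y, red, offset, phi)
    lr <- lrt(fit_group, fit_red)
    pmat[, si] <- lr$p
    qmat[, si] <- bh_fdr(lr$p)
    up[, si] <- lfc[, si] >= lfc_threshold & qmat[, si] < alpha_add
    down[, si] <- lfc[, si] <= -lfc_threshold & qmat[, si] < alpha_add
  }
  tab$is_ADD <- apply(qmat < alpha_add, 1L, function(r) any(r, na.rm = TRUE))
  colnames(lfc) <- paste0("logFC_", stages)
  colnames(pmat) <- paste0("p_", stages)
  colnames(qmat) <- paste0("q_", stages)
  colnames(up) <- paste0("up_", stages)
  colnames(down) <- paste0("down_", stages)
  tab <- cbind(tab, lfc, pmat, qmat, up, down)
  rownames(tab) <- NULL

  summary <- list(
    n_tested = nrow(tab),
    n_excluded_zero = n_excluded,
    n_asd = sum(tab$is_ASD, na.rm = TRUE),
    n_add = sum(tab$is_ADD, na.rm = TRUE),
    up_by_stage = colSums(up, na.rm = TRUE),
    down_by_stage = colSums(down, na.rm = TRUE))
  names(summary$up_by_stage) <- stages
  names(summary$down_by_stage) <- stages

  structure(list(table = tab, summary = summary, dispersion = dispersion,
                 stages = stages, genotypes = genotypes),
            class = "deg_result")
}

#' @export
print.deg_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("deg_result: %d genes tested (%d all-zero excluded)\n",
              s$n_tested, s$n_excluded_zero))
  cat(sprintf("  stage/genotype-dependent (ASD): %d\n", s$n_asd))
  cat(sprintf("  genotype-dependent (ADD):      %d\n", s$n_add))
  cat("  two-fold up by stage:  ", paste(s$up_by_stage, collapse = " "), "\n")
  cat("  two-fold down by stage:", paste(s$down_by_stage, collapse = " "), "\n")
  invisible(x)
}
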