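#' Draw per-gene expression programs with a controllable mutant stage delay
#'
#' Each gene gets an archetypal stage profile, a baseline mean, a log2
#' amplitude, a negative-binomial dispersion, and two mutant effects: a
#' one-stage expression delay (the mutant expresses the wild-type program
#' shifted one stage later, boundary value held) and/or a constant log2
#' level shift. Null genes are flat and unshifted. Delayed/null/shifted
#' gene numbers are fixed by deterministic quota (\code{round(n * frac)}).
#'
#' @param design a \code{\link{study_design}}.
#' @param n_genes number of genes (default taken from the design).
#' @param frac_delayed fraction of genes whose mutant program lags the WT
#'   program by one stage.
#' @param frac_null fraction of flat, genotype-independent genes.
#' @param frac_shifted fraction of genes carrying a constant mutant log2
#'   level shift (drawn on non-null genes).
#' @param archetype_weights probability weights over the non-flat
#'   archetypes (see \code{\link{archetype_profiles}}); uniform by default.
#' @param base_mean_meanlog,base_mean_sdlog log-normal parameters for the
#'   per-gene baseline mean count.
#' @param dispersion_meanlog,dispersion_sdlog log-normal parameters for the
#'   NB dispersion phi (variance = mu + phi mu^2).
#' @param amplitude_range range of the per-gene log2 swing.
#' @param shift_range range of the absolute mutant log2 level shift.
#' @param seed integer seed; results are fully reproducible given it.
#' @return A data frame of class \code{gene_programs} with one row per gene
#'   (gene_id, archetype, base_mean, amplitude, dispersion, delayed_in_mut,
#'   genotype_shift, is_null); the truth table for simulation-based
#'   validation is \code{\link{truth_table}} of this object.
#' @export
generate_programs <- function(design = study_design(),
                              n_genes = design$n_genes,
                              frac_delayed = 0.3,
                              frac_null = 0.2,
                              frac_shifted = 0.1,
                              archetype_weights = NULL,
                              base_mean_meanlog = log(50),
                              base_mean_sdlog = 1.2,
                              dispersion_meanlog = log(0.1),
                              dispersion_sdlog = 0.5,
                              amplitude_range = c(1, 3),
                              shift_range = c(0.5, 1.5),
                              seed = NULL) {
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 0L) stop("n_genes must be >= 0")
  for (f in c(frac_delayed, frac_null, frac_shifted))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  if (frac_delayed + frac_null > 1)
    stop("frac_delayed + frac_null must not exceed 1")

  arch <- archetype_profiles(length(design$stages))
  shapes <- setdiff(rownames(arch), "flat")
  if (is.null(archetype_weights)) {
    archetype_weights <- default_archetype_weights(shapes)
  }
  if (length(archetype_weights) != length(shapes))
    stop("archetype_weights must have one weight per non-flat archetype")
  if (any(archetype_weights < 0)) stop("archetype_weights must be non-negative")
  if (abs(sum(archetype_weights) - 1) > 1e-8)
    archetype_weights <- archetype_weights / sum(archetype_weights)

  if (n_genes == 0L) {
    out <- data.frame(gene_id = character(), archetype = character(),
                      base_mean = numeric(), amplitude = numeric(),
                      dispersion = numeric(), delayed_in_mut = logical(),
                      genotype_shift = numeric(), is_null = logical(),
                      stringsAsFactors = FALSE)
    class(out) <- c("gene_programs", class(out))
    attr(out, "stages") <- design$stages
    return(out)
  }

  if (!is.null(seed)) set.seed(as.integer(seed))
  gene_id <- sprintf("gene%06d", seq_len(n_genes))

  n_null <- round(n_genes * frac_null)
  n_delayed <- round(n_genes * frac_delayed)
  n_shifted <- round(n_genes * frac_shifted)

  perm <- sample.int(n_genes)
  null_idx <- perm[seq_len(n_null)]
  non_null <- if (n_null > 0) perm[-seq_len(n_null)] else perm
  if (n_delayed > length(non_null)) n_delayed <- length(non_null)
  delayed_idx <- non_null[seq_len(n_delayed)]
  shifted_pool <- sample(non_null)
  n_shifted <- min(n_shifted, length(shifted_pool))
  shifted_idx <- shifted_pool[seq_len(n_shifted)]

  archetype <- sample(shapes, n_genes, replace = TRUE, prob = archetype_weights)
  amplitude <- runif(n_genes, amplitude_range[1L], amplitude_range[2L])
  base_mean <- exp(rnorm(n_genes, base_mean_meanlog, base_mean_sdlog))
  dispersion <- exp(rnorm(n_genes, dispersion_meanlog, dispersion_sdlog))
  genotype_shift <- rep(0, n_genes)
  genotype_shift[shifted_idx] <-
    sample(c(-1, 1), n_shifted, replace = TRUE) *
    runif(n_shifted, shift_range[1L], shift_range[2L])
  delayed_in_mut <- rep(FALSE, n_genes)
  delayed_in_mut[delayed_idx] <- TRUE

  archetype[null_idx] <- "flat"
  amplitude[null_idx] <- 0
  genotype_shift[null_idx] <- 0
  is_null <- seq_len(n_genes) %in% null_idx

  out <- data.frame(gene_id, archetype, base_mean, amplitude, dispersion,
                    delayed_in_mut, genotype_shift, is_null,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_programs", class(out))
  attr(out, "stages") <- design$stages
  out
}

#' Per-gene simulation ground truth
#'
#' @param programs a \code{gene_programs} object.
#' @return data frame with archetype, delayed flag, genotype shift, null
#'   flag and the derived genotype-dependence flag \code{is_genotype_dep}
#'   (delayed or level-shifted, i.e. an autophagy-dependent gene in truth).
#' @export
truth_table <- function(programs) {
  data.frame(gene_id = programs$gene_id, archetype = programs$archetype,
             delayed_in_mut = programs$delayed_in_mut,
             genotype_shift = programs$genotype_shift,
             is_null = programs$is_null,
             is_genotype_dep = programs$delayed_in_mut |
               programs$genotype_shift != 0,
             stringsAsFactors = FALSE)
}

#' Noise-free expected log2 expression per genotype and stage
#'
#' @param programs a \code{gene_programs} object.
#' @param design the matching \code{\link{study_design}}.
#' @return named list, one genes x stages matrix per genotype, giving
#'   log2 of the relative expression level q used by the count sampler.
#' @export
expected_log2_expression <- function(programs, design) {
  arch <- archetype_profiles(length(design$stages))
  prof <- arch[programs$archetype, , drop = FALSE]
  out <- list()
  mut_genotypes <- setdiff(design$genotypes, design$genotypes[1L])
  for (g in design$genotypes) {
    p <- prof
    shift <- 0
    if (g %in% mut_genotypes) {
      p[programs$delayed_in_mut, ] <-
        t(apply(p[programs$delayed_in_mut, , drop = FALSE], 1L,
                shift_profile_right))
      shift <- programs$genotype_shift
    }
    m <- log2(programs$base_mean) + programs$amplitude * p + shift
    dimnames(m) <- list(programs$gene_id, design$stages)
    out[[g]] <- m
  }
  out
}

#' Stage of maximal expected genotype separation
#'
#' The stage at which the mean absolute log2 difference between mutant and
#' wild-type expected expression (over non-null genes) is largest -- the
#' stage where the simulated mutant phenotype is most visible.
#' @param programs a \code{gene_programs} object.
#' @param design the matching design.
#' @return stage label (character scalar).
#' @export
max_separation_stage <- function(programs, design) {
  ex <- expected_log2_expression(programs, design)
  ref <- design$genotypes[1L]
  mut <- design$genotypes[2L]
  keep <- !programs$is_null
  sep <- colMeans(abs(ex[[mut]][keep, , drop = FALSE] -
                      ex[[ref]][keep, , drop = FALSE]))
  names(which.max(sep))
}

#' Simulate a negative-binomial count matrix under a study design
#'
#' Entry (g, s) is NB-distributed with mean
#' \eqn{L_s q_{g,cond(s)} / \sum_g q_{g,cond(s)}} and dispersion
#' \eqn{\phi_g}, where q is the exponentiated program value for the
#' sample's genotype x stage and L_s a log-normal library size. Genes with
#' dispersion 0 are sampled as Poisson.
#'
#' @param programs a \code{gene_programs} object.
#' @param design the matching \code{\link{study_design}}.
#' @param libsize_log_sd SD of log library size (0 fixes all depths).
#' @param mean_libsize median library size in counts.
#' @param seed integer seed.
#' @return A \code{count_matrix}: list with integer \code{counts}
#'   (genes x samples) and the \code{samples} metadata data frame.
#' @export
simulate_counts <- function(programs, design,
                            libsize_log_sd = 0.2,
                            mean_libsize = 5e6,
                            seed = NULL) {
  if (nrow(programs) == 0L) stop("programs must be non-empty")
  if (mean_libsize <= 0) stop("mean_libsize must be > 0")
  samp <- design$samples
  bad <- !(samp$genotype %in% design$genotypes) |
    !(samp$stage %in% design$stages)
  if (any(bad)) stop("design samples contain unknown genotype or stage")

  if (!is.null(seed)) set.seed(as.integer(seed))
  ex <- expected_log2_expression(programs, design)
  q <- lapply(ex, function(m) 2^m)

  n_s <- nrow(samp)
  lib <- exp(rnorm(n_s, log(mean_libsize), libsize_log_sd))

  G <- nrow(programs)
  mu <- matrix(0, G, n_s, dimnames = list(programs$gene_id, samp$sample))
  for (j in seq_len(n_s)) {
    qg <- q[[samp$genotype[j]]][, samp$stage[j]]
    mu[, j] <- lib[j] * qg / sum(qg)
  }

  phi <- programs$dispersion
  counts <- matrix(0L, G, n_s, dimnames = dimnames(mu))
  pois <- phi < 1e-12
  if (any(pois)) {
    counts[pois, ] <- rpois(sum(pois) * n_s, as.vector(mu[pois, , drop = FALSE]))
  }
  if (any(!pois)) {
    nb_mu <- mu[!pois, , drop = FALSE]
    counts[!pois, ] <- rnbinom(sum(!pois) * n_s, mu = as.vector(nb_mu),
                               size = rep(1 / phi[!pois], times = n_s))
  }
  storage.mode(counts) <- "integer"
  count_matrix(counts, samp)
}

#' Generate a flat gene-to-term annotation with constructed enrichment
#'
#' Terms draw their member genes uniformly, except a chosen fraction of
#' terms that prefer delay-truth genes at a fixed odds ratio, giving known
#' positives for validating the over-representation analysis.
#'
#' @param truth a \code{\link{truth_table}} data frame.
#' @param n_terms number of terms.
#' @param genes_per_term genes annotated to each term (sampled without
#'   replacement).
#' @param frac_terms_enriched_in_delayed fraction of terms constructed to
#'   prefer delayed genes.
#' @param odds_ratio sampling weight of a delayed gene relative to a
#'   non-delayed one inside an enriched term.
#' @param seed integer seed.
#' @return data frame (gene_id, term_id) with the enriched term ids in
#'   attribute \code{"enriched_terms"}.
#' @export
generate_annotation <- function(truth, n_terms = 100L, genes_per_term = 50L,
                                frac_terms_enriched_in_delayed = 0.05,
                                odds_ratio = 5, seed = NULL) {
  n_terms <- as.integer(n_terms)
  if (is.na(n_terms) || n_terms < 1L) stop("n_terms must be >= 1")
  if (genes_per_term > nrow(truth))
    stop("genes_per_term exceeds the number of genes")
  if (frac_terms_enriched_in_delayed < 0 || frac_terms_enriched_in_delayed > 1)
    stop("frac_terms_enriched_in_delayed must lie in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))

  n_enr <- round(n_terms * frac_terms_enriched_in_delayed)
  term_id <- sprintf("TERM%04d", seq_len(n_terms))
  enriched <- term_id[seq_len(n_enr)]
  w_enr <- ifelse(truth$delayed_in_mut, odds_ratio, 1)

  rows <- lapply(seq_len(n_terms), function(i) {
    w <- if (term_id[i] %in% enriched) w_enr else rep(1, nrow(truth))
    data.frame(gene_id = sample(truth$gene_id, genes_per_term, prob = w),
               term_id = term_id[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "enriched_terms") <- enriched
  out
}

#' Generate a synthetic qPCR Ct table from expression programs
#'
#' For each selected gene and sample, the target threshold cycle is the
#' reference-gene Ct minus the log (base \code{efficiency}) of the gene's
#' expected expression, plus Gaussian cycle noise, so that
#' \eqn{Ct_{target} - Ct_{ref} = -\log_2(\mathrm{expression}) + noise}
#' at the default efficiency of 2.
#'
#' @param programs a \code{gene_programs} object (or subset of rows).
#' @param design the matching design.
#' @param genes gene ids to measure (default: up to 3 non-null genes).
#' @param reference_gene name of the reference transcript row added to
#'   every sample.
#' @param reference_ct baseline reference threshold cycle.
#' @param efficiency amplification fold per cycle (> 1; 2 for the
#'   2^-ddCt convention).
#' @param noise_sd SD of cycle noise (0 for a noise-free table).
#' @param seed integer seed.
#' @return data frame (sample, genotype, stage, replicate, gene, ct).
#' @export
generate_ct_table <- function(programs, design,
                              genes = NULL,
                              reference_gene = "OsUbiquitin5",
                              reference_ct = 20,
                              efficiency = 2,
                              noise_sd = 0,
                              seed = NULL) {
  if (efficiency <= 1) stop("efficiency must be > 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0 (0 for noise-free)")
  if (is.null(genes)) {
    cand <- programs$gene_id[!programs$is_null]
    genes <- cand[seq_len(min(3L, length(cand)))]
  }
  if (!all(genes %in% programs$gene_id)) stop("unknown gene in 'genes'")
  if (!is.null(seed)) set.seed(as.integer(seed))

  ex <- expected_log2_expression(programs, design)
  samp <- design$samples
  rows <- vector("list", length(genes) + 1L)
  log_eff <- log2(efficiency)
  for (i in seq_along(genes)) {
    g <- genes[i]
    lvl <- vapply(seq_len(nrow(samp)), function(j)
      ex[[samp$genotype[j]]][g, samp$stage[j]], numeric(1L))
    ct <- reference_ct - lvl / log_eff +
      (if (noise_sd > 0) rnorm(nrow(samp), 0, noise_sd) else 0)
    rows[[i]] <- data.frame(samp, gene = g, ct = ct,
                            stringsAsFactors = FALSE)
  }
  ref_ct <- reference_ct +
    (if (noise_sd > 0) rnorm(nrow(samp), 0, noise_sd) else 0)
  rows[[length(genes) + 1L]] <- data.frame(samp, gene = reference_gene,
                                           ct = ref_ct,
                                           stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
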