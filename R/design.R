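#' @useDynLib anthersom, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor cmdscale prcomp rnorm rpois rnbinom runif p.adjust
#'   pchisq phyper quantile sd hclust dist optimize setNames aggregate
#' @importFrom utils write.table read.delim packageVersion
NULL

#' Anther developmental stages profiled by the study
#'
#' Anthers are staged from tetrad (ST8) through early uninucleate (ST9),
#' late uninucleate early/late (ST10E, ST10L) to bicellular (ST11); tapetal
#' programmed cell death progresses across this window.
#' @export
ANTHER_STAGES <- c("ST8", "ST9", "ST10E", "ST10L", "ST11")

#' Genotype labels: wild type and the autophagy-deficient mutant
#' @export
ANTHER_GENOTYPES <- c("WT", "MUT")

#' Define a stage x genotype x replicate study design
#'
#' @param stages ordered character vector of developmental stage labels.
#' @param genotypes ordered character vector of genotype labels; the first
#'   is treated as the reference (wild type).
#' @param replicates_per_cell number of biological replicates for every
#'   genotype x stage combination.
#' @param n_genes number of genes the design is intended for (carried as
#'   metadata; the simulator uses it as its default).
#' @return An object of class \code{study_design} with a \code{samples}
#'   data frame (sample, genotype, stage, replicate); sample names follow
#'   \code{"{genotype}_{stage}_r{rep}"}.
#' @examples
#' d <- study_design(replicates_per_cell = 3)
#' nrow(d$samples)  # 30
#' @export
study_design <- function(stages = ANTHER_STAGES,
                         genotypes = ANTHER_GENOTYPES,
                         replicates_per_cell = 3L,
                         n_genes = 20000L) {
  stopifnot(length(stages) >= 1L, !anyDuplicated(stages),
            length(genotypes) >= 1L, !anyDuplicated(genotypes))
  replicates_per_cell <- as.integer(replicates_per_cell)
  if (is.na(replicates_per_cell) || replicates_per_cell < 1L)
    stop("replicates_per_cell must be a positive integer")
  grid <- expand.grid(replicate = seq_len(replicates_per_cell),
                      stage = stages, genotype = genotypes,
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    sample = sprintf("%s_%s_r%d", grid$genotype, grid$stage, grid$replicate),
    genotype = grid$genotype, stage = grid$stage,
    replicate = grid$replicate, stringsAsFactors = FALSE)
  structure(list(stages = stages, genotypes = genotypes,
                 replicates_per_cell = replicates_per_cell,
                 n_genes = as.integer(n_genes), samples = samples),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("study_design: %d stages x %d genotypes x %d replicates = %d samples\n",
              length(x$stages), length(x$genotypes), x$replicates_per_cell,
              nrow(x$samples)))
  invisible(x)
}

#' Archetypal stage-expression profiles
#'
#' A fixed library of expression shapes across the stage axis: monotone
#' induction, monotone repression, a transient peak at every stage
#' (including an early-high and a late-spike shape at the boundaries),
#' and a flat profile -- eight shapes for the five-stage design. All
#' non-flat profiles are mean-centered and variance-scaled (sample SD)
#' across stages, so a gene's \code{amplitude} directly sets its log2
#' swing; the flat profile is all zeros and is reserved for null genes.
#'
#' @param n_stages number of stages (>= 3).
#' @return numeric matrix, one row per archetype, \code{n_stages} columns.
#' @export
archetype_profiles <- function(n_stages = 5L) {
  n_stages <- as.integer(n_stages)
  stopifnot(n_stages >= 3L)
  s <- seq_len(n_stages)
  raw <- list(up = as.numeric(s), down = as.numeric(rev(s)))
  for (k in s) raw[[paste0("peak", k)]] <- as.numeric(s == k)
  std <- lapply(raw, function(v) (v - mean(v)) / sd(v))
  std$flat <- rep(0, n_stages)
  do.call(rbind, std)
}

# Default mixture over the non-flat archetypes. Transient peaks dominate
# and are weighted toward the mid-uninucleate window, where anther
# transcriptional programs turn over most sharply; for a 5-stage design
# the induced one-stage-delay phenotype is then maximally visible at the
# third stage (ST10E), as in the system being emulated.
default_archetype_weights <- function(shapes) {
  w <- setNames(rep(0, length(shapes)), shapes)
  peaks <- grep("^peak", shapes, value = TRUE)
  w[c("up", "down")] <- 0.15
  if (length(peaks) == 5L) {
    w[peaks] <- c(0.05, 0.15, 0.30, 0.05, 0.15)
  } else {
    w[peaks] <- 0.7 / length(peaks)
  }
  w
}

# Right-shift a profile by one stage, holding the boundary value: the
# delayed series at stage s reproduces the original at stage s-1.
shift_profile_right <- function(v) c(v[1L], v[-length(v)])
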