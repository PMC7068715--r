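#' Configuration for a full analysis run
#'
#' Collects every tunable constant of the chain in one validated object:
#' the DEG thresholds (stage/genotype FDR 0.01, per-stage genotype FDR
#' 0.05, two-fold rule), the total-CPM filter (> 10), the SOM geometry
#' (4 x 4 map for the stage-dependent set, 3 x 3 for the
#' genotype-dependent set, 100 batch iterations) and the displacement
#' distance cutoff (0.8), plus the simulator settings.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param outdir output directory.
#' @param n_genes,frac_delayed,frac_null,frac_shifted simulator settings
#'   (see \code{\link{generate_programs}}).
#' @param replicates_per_cell biological replicates per genotype x stage.
#' @param asd_fdr,add_fdr,lfc,cpm_sum,som_distance analysis thresholds.
#' @param asd_grid,add_grid SOM grid sizes (rows, cols).
#' @param som_iterations batch SOM iterations.
#' @param top_edges displacement edges taken forward to enrichment.
#' @param trim_m,trim_a,prior_count,mds_top_genes normalization and QC
#'   settings.
#' @param min_term_size,enrich_fdr enrichment settings.
#' @param n_terms,genes_per_term,frac_terms_enriched annotation simulator
#'   settings.
#' @return validated list of class \code{run_config}.
#' @export
run_config <- function(seed = 7L, outdir = "anthersom_run",
                       n_genes = 20000L, frac_delayed = 0.3,
                       frac_null = 0.2, frac_shifted = 0.1,
                       replicates_per_cell = 3L,
                       asd_fdr = 0.01, add_fdr = 0.05, lfc = 1,
                       cpm_sum = 10, som_distance = 0.8,
                       asd_grid = c(4L, 4L), add_grid = c(3L, 3L),
                       som_iterations = 100L, top_edges = 5L,
                       trim_m = 0.30, trim_a = 0.05, prior_count = 0.5,
                       mds_top_genes = 500L,
                       min_term_size = 5L, enrich_fdr = 0.05,
                       n_terms = 100L, genes_per_term = 50L,
                       frac_terms_enriched = 0.05) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  for (th in c("asd_fdr", "add_fdr", "lfc", "cpm_sum", "som_distance"))
    if (cfg[[th]] <= 0) stop(th, " must be positive")
  if (any(asd_grid < 2L) || any(add_grid < 2L))
    stop("SOM grids must be at least 2 x 2")
  structure(cfg, class = "run_config")
}

stage_seed <- function(cfg, k) (as.integer(cfg$seed) * 101L + k) %% 2000000000L

# Hash of the analysis-relevant configuration; the output location is
# not part of the analysis identity.
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$outdir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full simulate-to-enrichment analysis chain
#'
#' Executes, in dependency order: count simulation, TMM normalization and
#' sample QC, NB-GLM differential expression, per-genotype-scaled SOM on
#' the stage-dependent genes plus a WT-referenced SOM on the
#' genotype-dependent genes, the WT-to-mutant displacement network and
#' delay score, term enrichment of the top displacement sets, PCA and the
#' per-stage log2FC heatmap matrix, and ddCt quantification of the
#' simulated qPCR table. Every output is a TSV/JSON file under
#' \code{cfg$outdir}; a manifest records the configuration, its hash, and
#' an MD5 checksum per output so identical seeds reproduce identical
#' runs. When a manifest with the same configuration hash and intact
#' outputs already exists and \code{force} is FALSE, nothing is
#' recomputed.
#'
#' @param cfg a \code{\link{run_config}}.
#' @param force rerun even when up-to-date outputs exist.
#' @param quiet suppress per-stage progress messages.
#' @return the manifest (list), invisibly; also written as
#'   \code{manifest.json}.
#' @export
run_pipeline <- function(cfg = run_config(), force = FALSE, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  outdir <- cfg$outdir
  manifest_path <- file.path(outdir, "manifest.json")
  hash <- config_hash(cfg)

  if (!force && file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    paths <- file.path(outdir, names(old$files))
    if (identical(old$config_hash, hash) && all(file.exists(paths)) &&
        identical(unname(tools::md5sum(paths)), unname(unlist(old$files)))) {
      if (!quiet) message("outputs up to date; nothing to do (use force = TRUE)")
      return(invisible(old))
    }
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  files <- character()
  add <- function(path) files <<- c(files, path)

  ## 1. simulate
  say("[1/8] simulating counts (", cfg$n_genes, " genes)")
  design <- study_design(replicates_per_cell = cfg$replicates_per_cell,
                         n_genes = cfg$n_genes)
  programs <- generate_programs(design, n_genes = cfg$n_genes,
                                frac_delayed = cfg$frac_delayed,
                                frac_null = cfg$frac_null,
                                frac_shifted = cfg$frac_shifted,
                                seed = stage_seed(cfg, 1L))
  truth <- truth_table(programs)
  counts <- simulate_counts(programs, design, seed = stage_seed(cfg, 2L))
  annotation <- generate_annotation(truth, n_terms = cfg$n_terms,
                                    genes_per_term = min(cfg$genes_per_term,
                                                         nrow(truth)),
                                    frac_terms_enriched_in_delayed =
                                      cfg$frac_terms_enriched,
                                    seed = stage_seed(cfg, 3L))
  ct_tab <- generate_ct_table(programs, design, noise_sd = 0.1,
                              seed = stage_seed(cfg, 4L))
  add(write_df_tsv(truth, file.path(outdir, "truth.tsv")))
  write_counts_tsv(counts, file.path(outdir, "counts.tsv"),
                   file.path(outdir, "metadata.tsv"))
  add(file.path(outdir, "counts.tsv")); add(file.path(outdir, "metadata.tsv"))
  add(write_df_tsv(annotation, file.path(outdir, "annotation.tsv")))
  add(write_df_tsv(ct_tab, file.path(outdir, "ct.tsv")))

  ## 2. normalize + QC
  say("[2/8] TMM normalization and sample QC")
  stats <- tmm_factors(counts, trim_M = cfg$trim_m, trim_A = cfg$trim_a)
  cpm <- cpm_matrix(counts, stats)
  logcpm <- cpm_matrix(counts, stats, log2 = TRUE,
                       prior_count = cfg$prior_count)
  corr <- sample_correlation_matrix(logcpm)
  mds <- mds_embedding(logcpm, top_genes = cfg$mds_top_genes)
  add(write_df_tsv(as.data.frame(unclass(stats)),
                   file.path(outdir, "tmm_factors.tsv")))
  add(write_matrix_tsv(logcpm, file.path(outdir, "logcpm.tsv"), "gene_id"))
  add(write_matrix_tsv(corr, file.path(outdir, "correlation.tsv"), "sample"))
  add(write_matrix_tsv(mds$points, file.path(outdir, "mds.tsv"), "sample"))

  ## 3. differential expression
  say("[3/8] NB-GLM differential expression")
  deg <- classify_degs(counts, stats, stages = design$stages,
                       genotypes = design$genotypes,
                       alpha_asd = cfg$asd_fdr, alpha_add = cfg$add_fdr,
                       lfc_threshold = cfg$lfc)
  add(write_df_tsv(deg$table, file.path(outdir, "deg_table.tsv")))
  jsonlite::write_json(deg$summary, file.path(outdir, "deg_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  add(file.path(outdir, "deg_summary.json"))

  asd_genes <- deg$table$gene_id[deg$table$is_ASD %in% TRUE]
  add_genes <- deg$table$gene_id[deg$table$is_ADD %in% TRUE]

  ## 4. SOM clustering
  say("[4/8] SOM clustering (", length(asd_genes), " stage-dependent, ",
      length(add_genes), " genotype-dependent genes)")
  profiles <- stage_profiles(logcpm, design$samples,
                             stages = design$stages,
                             genotypes = design$genotypes)
  asd_prof <- structure(lapply(profiles, function(m)
    m[intersect(rownames(m), asd_genes), , drop = FALSE]),
    class = "stage_profiles", stages = design$stages)
  asd_scaled <- scale_profiles(asd_prof, "per-genotype-z")
  stacked <- do.call(rbind, lapply(names(asd_scaled), function(g) {
    m <- asd_scaled[[g]]; rownames(m) <- paste(rownames(m), g, sep = "|"); m
  }))
  asd_som <- train_som(stacked, cfg$asd_grid[1L], cfg$asd_grid[2L],
                       iterations = cfg$som_iterations)
  assign_wt <- som_assign(asd_som, asd_scaled[[design$genotypes[1L]]])
  assign_mut <- som_assign(asd_som, asd_scaled[[design$genotypes[2L]]])
  both <- rbind(cbind(assign_wt, genotype = design$genotypes[1L]),
                cbind(assign_mut, genotype = design$genotypes[2L]))
  add(write_matrix_tsv(asd_som$prototypes,
                       file.path(outdir, "som_asd_prototypes.tsv"), "unit"))
  add(write_df_tsv(both, file.path(outdir, "som_asd_assignments.tsv")))
  add(write_df_tsv(cluster_counts(both, prod(cfg$asd_grid)),
                   file.path(outdir, "som_asd_counts.tsv")))

  keep_cpm <- filter_total_cpm(cpm, cfg$cpm_sum)
  add_kept <- intersect(add_genes, keep_cpm)
  add_prof <- structure(lapply(profiles, function(m)
    m[add_kept, , drop = FALSE]),
    class = "stage_profiles", stages = design$stages)
  add_scaled <- scale_profiles(add_prof, "wt-referenced")
  if (nrow(add_scaled[[1L]]) >= prod(cfg$add_grid)) {
    add_som <- train_som(add_scaled[[1L]], cfg$add_grid[1L], cfg$add_grid[2L],
                         iterations = cfg$som_iterations)
    add_assign <- som_assign(add_som, add_scaled[[1L]])
    add(write_matrix_tsv(add_som$prototypes,
                         file.path(outdir, "som_add_prototypes.tsv"), "unit"))
  } else {
    say("  too few genes pass the total-CPM filter for the ",
        cfg$add_grid[1L], " x ", cfg$add_grid[2L], " map; writing empty outputs")
    add_assign <- data.frame(id = character(), unit = integer(),
                             distance = numeric())
  }
  add(write_df_tsv(add_assign, file.path(outdir, "som_add_assignments.tsv")))
  add(write_df_tsv(cluster_counts(add_assign, prod(cfg$add_grid)),
                   file.path(outdir, "som_add_counts.tsv")))

  ## 5. displacement network
  say("[5/8] displacement network")
  disp <- displaced_genes(assign_wt, assign_mut,
                          max_distance = cfg$som_distance)
  network <- build_network(disp, prod(cfg$asd_grid))
  top <- top_displacements(network, cfg$top_edges)
  succ <- cluster_successors(asd_som)
  dscore <- delay_score(disp, succ)
  add(write_df_tsv(network$edges, file.path(outdir, "displacement_edges.tsv")))
  add(write_df_tsv(disp$displaced,
                   file.path(outdir, "displacement_members.tsv")))
  add(write_displacement_graphml(network,
                                 file.path(outdir, "displacement.graphml")))
  jsonlite::write_json(
    list(displaced_total = network$displaced_total,
         counts = as.list(disp$counts), delay_score = dscore$score,
         delay_n_scored = dscore$n_scored),
    file.path(outdir, "displacement_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  add(file.path(outdir, "displacement_summary.json"))

  ## 6. enrichment of top displacement sets
  say("[6/8] term enrichment of top displacements")
  universe <- intersect(asd_genes, unique(assign_wt$id))
  enr <- enrich_displacements(top, universe, annotation,
                              min_term_size = cfg$min_term_size)
  enr_tab <- do.call(rbind, Map(function(edge, tab)
    if (nrow(tab) > 0L) cbind(displacement = edge, tab) else NULL,
    names(enr), enr))
  if (is.null(enr_tab))
    enr_tab <- data.frame(displacement = character(), term_id = character())
  rownames(enr_tab) <- NULL
  add(write_df_tsv(enr_tab, file.path(outdir, "enrichment.tsv")))

  ## 7. ordination
  say("[7/8] PCA and log2FC heatmap matrix")
  if (length(add_genes) >= 2L) {
    pca <- pca_samples(t(logcpm[add_genes, , drop = FALSE]))
    add(write_matrix_tsv(pca$scores, file.path(outdir, "pca_scores.tsv"),
                         "sample"))
    add(write_df_tsv(data.frame(component = seq_along(pca$eigenvalues),
                                eigenvalue = pca$eigenvalues,
                                variance_explained = pca$variance_explained,
                                cumulative = pca$cumulative),
                     file.path(outdir, "pca_variance.tsv")))
    heat <- logfc_heatmap_matrix(deg, add_genes)
    add(write_matrix_tsv(heat, file.path(outdir, "logfc_heatmap.tsv"),
                         "gene_id"))
  }

  ## 8. ddCt
  say("[8/8] ddCt quantification")
  rel <- ddct(ct_tab, reference_gene = "OsUbiquitin5",
              calibrator = c(design$genotypes[1L], design$stages[1L]))
  add(write_df_tsv(rel, file.path(outdir, "ddct_levels.tsv")))

  manifest <- list(
    package = "anthersom",
    version = as.character(packageVersion("anthersom")),
    seed = cfg$seed,
    config = unclass(cfg),
    config_hash = hash,
    files = as.list(setNames(unname(tools::md5sum(files)),
                             basename(files))))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
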