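#' Hypergeometric over-representation of annotation terms in a gene set
#'
#' For each term with at least \code{min_term_size} annotated genes in
#' the universe, tests whether the gene set contains more of the term's
#' genes than expected under hypergeometric sampling:
#' p = P[X >= set_hits] for X ~ Hypergeometric(universe_size,
#' universe_hits, set_size). BH FDR is computed across the tested terms
#' and results are sorted by p. Annotation is taken as flat (no term
#' hierarchy propagation).
#'
#' @param gene_set character vector, must be a subset of the universe.
#' @param universe character vector of background genes.
#' @param annotation data frame (gene_id, term_id); genes outside the
#'   universe are ignored.
#' @param min_term_size smallest universe term size tested.
#' @return data frame: term_id, set_hits, set_size, universe_hits,
#'   universe_size, fold_enrichment, p, q.
#' @export
enrich <- function(gene_set, universe, annotation, min_term_size = 5L) {
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  offenders <- setdiff(gene_set, universe)
  if (length(offenders) > 0L)
    stop("gene_set not contained in universe: ",
         paste(utils::head(offenders, 5L), collapse = ", "),
         if (length(offenders) > 5L) ", ..." else "")
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  empty <- data.frame(term_id = character(), set_hits = integer(),
                      set_size = integer(), universe_hits = integer(),
                      universe_size = integer(), fold_enrichment = numeric(),
                      p = numeric(), q = numeric(), stringsAsFactors = FALSE)
  if (nrow(ann) == 0L) return(empty)

  term_genes <- split(unique(ann[c("gene_id", "term_id")])$gene_id,
                      unique(ann[c("gene_id", "term_id")])$term_id)
  term_genes <- term_genes[lengths(term_genes) >= min_term_size]
  if (length(term_genes) == 0L || length(gene_set) == 0L) return(empty)

  N <- length(universe)
  n <- length(gene_set)
  K <- lengths(term_genes)
  k <- vapply(term_genes, function(g) sum(g %in% gene_set), integer(1L))
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  fold <- if (n > 0) (k / n) / (K / N) else rep(NA_real_, length(K))
  out <- data.frame(term_id = names(term_genes),
                    set_hits = unname(k), set_size = n,
                    universe_hits = unname(K), universe_size = N,
                    fold_enrichment = unname(fold),
                    p = unname(p), q = unname(bh_fdr(p)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Term enrichment of the top displacement gene sets
#'
#' Runs \code{\link{enrich}} independently on each edge's member genes
#' (intersected with the universe), each table BH-corrected on its own.
#'
#' @param top_edges result of \code{\link{top_displacements}} (edges with
#'   a \code{members} list column).
#' @param universe background gene set.
#' @param annotation gene-to-term map.
#' @param min_term_size smallest universe term size tested.
#' @return named list of enrichment tables, one per edge
#'   (names "wt->mut"); empty memberships give empty tables with a
#'   warning.
#' @export
enrich_displacements <- function(top_edges, universe, annotation,
                                 min_term_size = 5L) {
  out <- list()
  for (i in seq_len(nrow(top_edges))) {
    key <- paste0(top_edges$wt_cluster[i], "->", top_edges$mut_cluster[i])
    genes <- intersect(top_edges$members[[i]], universe)
    if (length(genes) == 0L)
      warning("displacement ", key, " has no member genes in the universe")
    out[[key]] <- enrich(genes, universe, annotation, min_term_size)
  }
  out
}
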