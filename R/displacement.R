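#' Genes displaced between WT and mutant SOM clusters
#'
#' A gene is displaced when its WT-profile and mutant-profile winning
#' units differ and it sits close to its cluster prototypes: distances
#' must be strictly below \code{max_distance} (in the scaled space the map
#' was trained in). The filter applies to both genotypes by default and is
#' configurable to one side only.
#'
#' @param assign_wt,assign_mut \code{\link{som_assign}} results for the
#'   same genes against the same grid.
#' @param max_distance strict distance cutoff.
#' @param filter which genotype's distance the cutoff applies to.
#' @return list: \code{displaced} data frame (gene_id, wt_cluster,
#'   mut_cluster), and bookkeeping counts (same_cluster, filtered_out,
#'   single_genotype, displaced).
#' @export
displaced_genes <- function(assign_wt, assign_mut, max_distance = 0.8,
                            filter = c("both", "wt", "mut", "none")) {
  filter <- match.arg(filter)
  common <- intersect(assign_wt$id, assign_mut$id)
  n_single <- length(union(assign_wt$id, assign_mut$id)) - length(common)
  w <- assign_wt[match(common, assign_wt$id), ]
  m <- assign_mut[match(common, assign_mut$id), ]

  near <- switch(filter,
    both = w$distance < max_distance & m$distance < max_distance,
    wt = w$distance < max_distance,
    mut = m$distance < max_distance,
    none = rep(TRUE, length(common)))
  moved <- w$unit != m$unit
  keep <- near & moved

  list(displaced = data.frame(gene_id = common[keep],
                              wt_cluster = w$unit[keep],
                              mut_cluster = m$unit[keep],
                              stringsAsFactors = FALSE),
       counts = c(displaced = sum(keep),
                  same_cluster = sum(!moved),
                  filtered_out = sum(moved & !near),
                  single_genotype = n_single),
       max_distance = max_distance, filter = filter)
}

#' Build the WT-to-mutant cluster displacement network
#'
#' One directed edge per ordered (wt_cluster, mut_cluster) pair observed
#' among displaced genes, weighted by gene count and percent of all
#' displaced genes; self-pairs cannot occur by construction. Isolated
#' units are kept as nodes so the grid geometry survives export.
#'
#' @param displaced result of \code{\link{displaced_genes}} (or its
#'   \code{displaced} data frame).
#' @param n_units number of SOM units (nodes).
#' @return object of class \code{displacement_network}: edges data frame
#'   (wt_cluster, mut_cluster, gene_count, percent), member gene lists per
#'   edge, displaced_total, nodes.
#' @export
build_network <- function(displaced, n_units) {
  df <- if (is.data.frame(displaced)) displaced else displaced$displaced
  total <- nrow(df)
  if (total == 0L) {
    edges <- data.frame(wt_cluster = integer(), mut_cluster = integer(),
                        gene_count = integer(), percent = numeric())
    members <- list()
  } else {
    key <- paste(df$wt_cluster, df$mut_cluster, sep = "->")
    members <- split(df$gene_id, key)
    pairs <- do.call(rbind, strsplit(names(members), "->", fixed = TRUE))
    edges <- data.frame(wt_cluster = as.integer(pairs[, 1L]),
                        mut_cluster = as.integer(pairs[, 2L]),
                        gene_count = lengths(members),
                        stringsAsFactors = FALSE)
    edges$percent <- 100 * edges$gene_count / total
    o <- order(edges$wt_cluster, edges$mut_cluster)
    edges <- edges[o, ]
    members <- members[o]
    rownames(edges) <- NULL
  }
  structure(list(edges = edges, members = members,
                 displaced_total = total, nodes = seq_len(n_units)),
            class = "displacement_network")
}

#' @export
print.displacement_network <- function(x, ...) {
  cat(sprintf("displacement_network: %d displaced genes on %d edges (%d units)\n",
              x$displaced_total, nrow(x$edges), length(x$nodes)))
  invisible(x)
}

#' Top displacement edges by gene count
#'
#' @param network a \code{\link{build_network}} result.
#' @param k number of edges (all edges if k exceeds the edge count).
#' @return edges data frame sorted by gene count descending, ties broken
#'   by (wt, mut) lexicographic order, with a \code{members} list column.
#' @export
top_displacements <- function(network, k = 5L) {
  if (k < 1L) stop("k must be >= 1")
  e <- network$edges
  if (nrow(e) == 0L) return(cbind(e, members = I(list())))
  o <- order(-e$gene_count, e$wt_cluster, e$mut_cluster)
  o <- o[seq_len(min(k, length(o)))]
  out <- e[o, ]
  out$members <- I(unname(network$members[o]))
  rownames(out) <- NULL
  out
}

#' Map each SOM cluster to its one-stage-delayed counterpart
#'
#' Shifts every prototype one stage to the right (boundary value held,
#' the same construction the simulator uses for delayed genes) and
#' re-assigns it to the map. A cluster whose delayed prototype wins its
#' own unit has no informative successor and is returned as NA.
#'
#' @param grid a \code{som_grid} whose features are ordered stages.
#' @return integer vector, successor unit per unit (NA when the successor
#'   is the unit itself).
#' @export
cluster_successors <- function(grid) {
  shifted <- t(apply(grid$prototypes, 1L, shift_profile_right))
  succ <- som_assign(grid, shifted)$unit
  succ[succ == seq_along(succ)] <- NA_integer_
  succ
}

#' Fraction of displaced genes moving to the one-stage-later cluster
#'
#' Quantifies the delay hypothesis: among displaced genes whose WT
#' cluster has an informative successor (see
#' \code{\link{cluster_successors}}), the fraction whose mutant cluster
#' is exactly that successor. On simulated data this score is much larger
#' for truth-delayed genes than for others.
#'
#' @param displaced the \code{displaced} data frame (or
#'   \code{\link{displaced_genes}} result).
#' @param successors successor map from \code{\link{cluster_successors}}.
#' @param genes optional gene id subset to score.
#' @return list: score in [0, 1] (NaN when no gene qualifies), n_scored,
#'   n_excluded (genes whose WT cluster lacks a successor).
#' @export
delay_score <- function(displaced, successors, genes = NULL) {
  df <- if (is.data.frame(displaced)) displaced else displaced$displaced
  if (!is.null(genes)) df <- df[df$gene_id %in% genes, , drop = FALSE]
  succ <- successors[df$wt_cluster]
  valid <- !is.na(succ)
  list(score = mean(df$mut_cluster[valid] == succ[valid]),
       n_scored = sum(valid), n_excluded = sum(!valid))
}

#' Export a displacement network for external renderers
#'
#' @param network a \code{\link{build_network}} result.
#' @param path output GraphML file.
#' @return the path, invisibly.
#' @export
write_displacement_graphml <- function(network, path) {
  g <- igraph::make_empty_graph(n = length(network$nodes), directed = TRUE)
  igraph::V(g)$name <- as.character(network$nodes)
  if (nrow(network$edges) > 0L) {
    el <- rbind(as.character(network$edges$wt_cluster),
                as.character(network$edges$mut_cluster))
    g <- igraph::add_edges(g, as.vector(el))
    igraph::E(g)$gene_count <- network$edges$gene_count
    igraph::E(g)$percent <- network$edges$percent
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
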