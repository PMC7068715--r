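#' Per-genotype stage profiles from log expression
#'
#' Summarizes replicate samples into one expression value per gene per
#' genotype per stage (arithmetic mean of log2-CPM over replicates).
#'
#' @param logcpm genes x samples matrix.
#' @param samples sample metadata data frame (sample, genotype, stage).
#' @param stages,genotypes level orders; defaults from the metadata.
#' @return object of class \code{stage_profiles}: named list of
#'   genes x stages matrices, one per genotype.
#' @export
stage_profiles <- function(logcpm, samples, stages = NULL, genotypes = NULL) {
  if (is.null(stages)) stages <- unique(samples$stage)
  if (is.null(genotypes)) genotypes <- unique(samples$genotype)
  out <- list()
  for (g in genotypes) {
    m <- matrix(NA_real_, nrow(logcpm), length(stages),
                dimnames = list(rownames(logcpm), stages))
    for (st in stages) {
      cols <- samples$sample[samples$genotype == g & samples$stage == st]
      if (length(cols) == 0L)
        stop("no replicates for genotype ", g, " at stage ", st)
      m[, st] <- rowMeans(logcpm[, cols, drop = FALSE])
    }
    out[[g]] <- m
  }
  structure(out, class = "stage_profiles", stages = stages)
}

#' Scale stage profiles for shape-based clustering
#'
#' Two modes. \code{"per-genotype-z"}: each gene's profile is
#' mean-centered and variance-scaled within each genotype separately, so
#' clustering sees expression shape, not magnitude, and the two genotypes
#' are directly comparable on one map. \code{"wt-referenced"}: the mutant
#' profile is centered and scaled by the wild-type per-gene mean and SD,
#' so deviations of the mutant from the WT program remain visible.
#' Genes whose scaling SD is zero are dropped (count reported in the
#' \code{"n_dropped"} attribute).
#'
#' @param profiles a \code{\link{stage_profiles}} object.
#' @param mode scaling mode.
#' @return list of scaled genes x stages matrices: both genotypes for
#'   per-genotype-z, the mutant only for wt-referenced.
#' @export
scale_profiles <- function(profiles, mode = c("per-genotype-z", "wt-referenced")) {
  mode <- match.arg(mode)
  genos <- names(profiles)
  if (mode == "per-genotype-z") {
    scaled <- lapply(profiles, function(m) {
      mu <- rowMeans(m)
      s <- apply(m, 1L, sd)
      z <- (m - mu) / s
      z[s > 0, , drop = FALSE]
    })
    common <- Reduce(intersect, lapply(scaled, rownames))
    n_dropped <- nrow(profiles[[1L]]) - length(common)
    scaled <- lapply(scaled, function(m) m[common, , drop = FALSE])
  } else {
    wt <- profiles[[1L]]
    mu <- rowMeans(wt)
    s <- apply(wt, 1L, sd)
    keep <- s > 0
    n_dropped <- sum(!keep)
    scaled <- lapply(profiles[-1L], function(m)
      ((m - mu) / s)[keep, , drop = FALSE])
  }
  attr(scaled, "mode") <- mode
  attr(scaled, "n_dropped") <- n_dropped
  scaled
}

# Row-major grid coordinates for unit indices 1..rows*cols.
grid_coords <- function(rows, cols) {
  u <- seq_len(rows * cols)
  cbind(row = (u - 1L) %/% cols + 1L, col = (u - 1L) %% cols + 1L)
}

squared_distances <- function(x, proto) {
  # N x K matrix of squared Euclidean distances
  d2 <- outer(rowSums(x^2), rep(1, nrow(proto))) +
    outer(rep(1, nrow(x)), rowSums(proto^2)) - 2 * x %*% t(proto)
  pmax(d2, 0)
}

#' Train a batch self-organizing map on a rectangular grid
#'
#' Batch Kohonen training: every iteration assigns each vector to its
#' nearest prototype, then replaces each prototype with the Gaussian
#' neighborhood-weighted mean of all vectors, the neighborhood truncated
#' at the current radius (a unit whose total weight vanishes keeps its
#' previous prototype). The radius decays linearly from
#' \code{max(rows, cols)/2} to 0.5 over the iterations, so training ends
#' with each unit refining on its own members alone.
#' Initialization is either the regular grid spanned by the first two
#' principal axes of the data (deterministic) or a seeded random sample
#' of data points.
#'
#' @param x vectors x features matrix (scaled stage profiles).
#' @param rows,cols grid dimensions; units are indexed row-major from 1.
#' @param iterations number of batch iterations (0 returns the
#'   initialization unchanged).
#' @param seed integer seed (used by \code{init = "sample"}).
#' @param init initialization scheme.
#' @return object of class \code{som_grid}: prototypes (units x features),
#'   rows, cols, coords, and training metadata.
#' @export
train_som <- function(x, rows, cols, iterations = 100L, seed = NULL,
                      init = c("pca", "sample")) {
  init <- match.arg(init)
  x <- as.matrix(x)
  K <- rows * cols
  if (nrow(x) < K) stop("need at least rows*cols vectors")
  coords <- grid_coords(rows, cols)

  if (init == "pca") {
    cen <- colMeans(x)
    sv <- svd(sweep(x, 2L, cen), nu = 0L, nv = 2L)
    sdev <- sv$d / sqrt(nrow(x) - 1L)
    a1 <- seq(-2, 2, length.out = cols) * sdev[1L]
    a2 <- if (ncol(sv$v) > 1L) seq(-2, 2, length.out = rows) * sdev[2L] else rep(0, rows)
    proto <- matrix(cen, K, ncol(x), byrow = TRUE) +
      outer(a1[coords[, "col"]], sv$v[, 1L]) +
      (if (ncol(sv$v) > 1L) outer(a2[coords[, "row"]], sv$v[, 2L]) else 0)
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    proto <- x[sample.int(nrow(x), K), , drop = FALSE]
  }
  rownames(proto) <- paste0("unit", seq_len(K))

  grid_d2 <- as.matrix(dist(coords))^2
  radii <- if (iterations > 0)
    seq(max(rows, cols) / 2, 0.5, length.out = iterations) else numeric()

  for (t in seq_len(iterations)) {
    d2 <- squared_distances(x, proto)
    winners <- max.col(-d2, ties.method = "first")
    # Gaussian weights truncated at the current radius; once the radius
    # drops below the unit spacing each prototype refines on its own
    # cluster alone (k-means-like final convergence)
    H <- exp(-grid_d2 / (2 * radii[t]^2)) * (sqrt(grid_d2) <= radii[t])
    W <- H[winners, , drop = FALSE]        # weight of vector i on unit k
    denom <- colSums(W)
    numer <- crossprod(W, x)
    upd <- denom > 1e-12
    proto[upd, ] <- numer[upd, , drop = FALSE] / denom[upd]
  }
  structure(list(prototypes = proto, rows = rows, cols = cols,
                 coords = coords, iterations = iterations,
                 init = init, seed = seed),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("som_grid: %d x %d rectangular, %d iterations (%s init)\n",
              x$rows, x$cols, x$iterations, x$init))
  invisible(x)
}

#' Assign vectors to their winning SOM units
#'
#' @param grid a \code{\link{train_som}} result.
#' @param x vectors x features matrix with the same feature count as the
#'   prototypes.
#' @return data frame: id, unit (argmin Euclidean distance, ties broken
#'   by the lowest unit index), distance.
#' @export
som_assign <- function(grid, x) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(grid$prototypes))
    stop("vector length does not match prototype length")
  d2 <- squared_distances(x, grid$prototypes)
  unit <- max.col(-d2, ties.method = "first")
  data.frame(id = rownames(x), unit = unit,
             distance = sqrt(d2[cbind(seq_len(nrow(x)), unit)]),
             stringsAsFactors = FALSE)
}

#' Tally genes per SOM cluster
#'
#' @param assignments a \code{\link{som_assign}} data frame, optionally
#'   with a \code{genotype} column to tally per genotype.
#' @param n_units total number of units (empty units are reported as 0).
#' @return data frame: (genotype,) unit, count, percent of that
#'   genotype's assigned genes.
#' @export
cluster_counts <- function(assignments, n_units) {
  tally <- function(df) {
    cnt <- tabulate(df$unit, nbins = n_units)
    data.frame(unit = seq_len(n_units), count = cnt,
               percent = if (sum(cnt) > 0) 100 * cnt / sum(cnt) else 0)
  }
  if (!is.null(assignments$genotype)) {
    parts <- lapply(split(assignments, assignments$genotype), tally)
    out <- do.call(rbind, Map(function(g, d) cbind(genotype = g, d),
                              names(parts), parts))
    rownames(out) <- NULL
    out
  } else {
    tally(assignments)
  }
}

#' Mean distance of vectors to their winning prototypes
#' @param grid a \code{som_grid}.
#' @param x data matrix.
#' @return quantization error (scalar).
#' @export
quantization_error <- function(grid, x) {
  mean(som_assign(grid, x)$distance)
}
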