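#' Fit a batch self-organizing map
#'
#' Features are z-scaled per column (parameters stored on the object), node
#' codebooks are initialized from randomly sampled data rows, and training
#' uses deterministic batch updates: every iteration assigns each row to its
#' best-matching unit (BMU) and replaces each codebook vector with the
#' Gaussian-neighborhood-weighted mean of the assigned rows. The
#' neighborhood radius decays linearly from half the grid diagonal to 0.5
#' node spacings, so training anneals from global ordering to local
#' refinement. Batch updates make the fit independent of row order and
#' reproducible from the seed alone.
#'
#' @param x Numeric matrix (rows = observations) or a `caf_composition`
#'   (non-empty neighborhoods are used).
#' @param grid_shape SOM lattice dimensions, e.g. `c(10, 10)`.
#' @param iterations Number of batch updates.
#' @param seed Integer seed (codebook initialization).
#' @return A `caf_som`: list with `codebook` (nodes x features, on the
#'   scaled scale), `node_xy`, `center`, `scale`, `grid_shape`,
#'   `iterations`, `seed`.
#' @export
fit_som <- function(x, grid_shape = c(10, 10), iterations = 60, seed = 1L) {
  if (inherits(x, "caf_composition")) {
    x <- composition_features(x)[!x$empty, , drop = FALSE]
  }
  x <- as.matrix(x)
  n_nodes <- prod(grid_shape)
  if (nrow(x) < n_nodes) {
    abort(paste0("Only ", nrow(x), " rows for ", n_nodes,
                 " SOM nodes; use a smaller `grid_shape`."))
  }
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")

  node_xy <- as.matrix(expand.grid(gx = seq_len(grid_shape[1]),
                                   gy = seq_len(grid_shape[2])))
  node_d2 <- cross_dist2(node_xy, node_xy)
  codebook <- withr::with_seed(seed, xs[sample.int(nrow(xs), n_nodes), , drop = FALSE])

  # anneal from global ordering to a hard-assignment (Lloyd) refinement over
  # the last fifth of training; dead nodes keep their current vector
  sigma0 <- sqrt(sum((grid_shape - 1)^2)) / 2
  for (it in seq_len(iterations)) {
    sigma <- max(sigma0 * (1 - (it - 1) / ceiling(0.8 * iterations)), 0.05)
    bmu <- max.col(-cross_dist2(xs, codebook), ties.method = "first")
    h <- exp(-node_d2 / (2 * sigma^2))        # nodes x nodes
    s <- matrix(0, n_nodes, ncol(xs))
    tmp <- rowsum(xs, bmu)
    s[as.integer(rownames(tmp)), ] <- tmp
    cnt <- tabulate(bmu, nbins = n_nodes)
    num <- h %*% s
    den <- as.numeric(h %*% cnt)
    live <- den > 0
    codebook[live, ] <- (num / den)[live, , drop = FALSE]
  }
  structure(
    list(codebook = codebook, node_xy = node_xy, center = center,
         scale = scale_, grid_shape = grid_shape, iterations = iterations,
         seed = seed),
    class = "caf_som"
  )
}

som_scale <- function(som, x) {
  sweep(sweep(as.matrix(x), 2, som$center), 2, som$scale, "/")
}

som_bmu <- function(som, x_scaled) {
  max.col(-cross_dist2(x_scaled, som$codebook), ties.method = "first")
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-case ratio `(s_i + s_j) / d(c_i, c_j)`,
#' where `s_i` is a cluster's mean Euclidean distance to its centroid and
#' `d` the centroid separation. Lower is better.
#'
#' @param x Numeric matrix of observations.
#' @param labels Cluster labels (one per row, >= 2 non-empty clusters).
#' @return The index (single number).
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(100, 0), ncol = 2), matrix(rnorm(100, 10), ncol = 2))
#' davies_bouldin(x, rep(1:2, each = 25))
davies_bouldin <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.vector(labels)
  if (length(labels) != nrow(x)) abort("`labels` must have one entry per row of `x`.")
  lv <- sort(unique(labels))
  k <- length(lv)
  if (k < 2) abort("Davies-Bouldin needs at least 2 clusters.")
  cent <- rowsum(x, factor(labels, levels = lv)) / as.vector(table(factor(labels, levels = lv)))
  sig <- vapply(seq_len(k), function(i) {
    rows <- x[labels == lv[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(rows, 2, cent[i, ])^2)))
  }, numeric(1))
  d <- sqrt(cross_dist2(cent, cent))
  if (any(d[upper.tri(d)] < .Machine$double.eps)) {
    abort("Coincident cluster centroids; Davies-Bouldin is undefined.")
  }
  r <- outer(sig, sig, "+") / d
  diag(r) <- -Inf
  mean(apply(r, 1, max))
}

#' Cluster neighborhoods into tissue regions
#'
#' Fits one SOM on the neighborhood composition vectors, then, for every
#' candidate region count `k`, meta-clusters the codebook vectors by Ward
#' linkage (weighted by node occupancy, so codebook nodes summarizing many
#' neighborhoods count accordingly), propagates node labels to neighborhoods
#' via their BMU, and scores the labeling with the Davies-Bouldin index on
#' the (scaled) neighborhood vectors. The selected `k` minimizes the index
#' (ties go to the smaller `k`); the full curve is retained for inspection.
#'
#' Empty neighborhoods are always excluded. Sparse neighborhoods -- fewer
#' cells than `min_cells` -- are additionally excluded from model fitting
#' and label propagation (they are mostly tissue-margin raster points whose
#' composition estimates are noise-dominated); they stay in the spatial map
#' as background.
#'
#' @param comp A `caf_composition`; pass a fraction-normalized one
#'   ([normalize_composition()]) to cluster on composition fractions, the
#'   package's recommended input, or raw counts to mirror the upstream
#'   tool's convention.
#' @param k_range Candidate region counts (integer vector, each >= 2 and
#'   <= number of SOM nodes).
#' @param som_shape,iterations,seed Passed to [fit_som()].
#' @param db_on `"neighborhoods"` (default) or `"nodes"`: the observations
#'   on which the index is computed.
#' @param min_cells Minimum cells per neighborhood to enter clustering;
#'   `"auto"` (default) uses 40% of the median cell count of non-empty
#'   neighborhoods. Set to 1 to keep every non-empty neighborhood.
#' @return A `caf_region_model`: list with `som`, `db_curve` (tibble `k`,
#'   `db`), `k`, `labels` (per-neighborhood region, `NA` for empty or
#'   sparse neighborhoods), `node_region`, `comp_meta` (grid
#'   ids/coords/empty flags), plus bookkeeping.
#' @export
cluster_regions <- function(comp, k_range = 2:15, som_shape = c(10, 10),
                            iterations = 60, seed = 1L,
                            db_on = c("neighborhoods", "nodes"),
                            min_cells = "auto") {
  db_on <- match.arg(db_on)
  if (!inherits(comp, "caf_composition")) abort("`comp` must come from compute_neighborhoods().")
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range)) abort("`k_range` must not be empty.")
  if (any(k_range < 2) || any(k_range > prod(som_shape))) {
    abort("`k_range` must lie within [2, number of SOM nodes].")
  }
  if (identical(min_cells, "auto")) {
    min_cells <- 0.4 * median(comp$total[!comp$empty])
  }
  keep <- !comp$empty & comp$total >= min_cells
  feats <- composition_features(comp)[keep, , drop = FALSE]
  som <- fit_som(feats, grid_shape = som_shape, iterations = iterations, seed = seed)
  xs <- som_scale(som, feats)
  bmu <- som_bmu(som, xs)
  occupancy <- tabulate(bmu, nbins = nrow(som$codebook))
  # ward.D on squared distances with `members` = occupancy-weighted Ward
  hc <- hclust(dist(som$codebook)^2, method = "ward.D",
               members = pmax(occupancy, 1e-9))

  db <- vapply(k_range, function(k) {
    node_lab <- cutree(hc, k = k)
    lab <- node_lab[bmu]
    if (length(unique(lab)) < 2) return(Inf)
    if (db_on == "neighborhoods") davies_bouldin(xs, lab)
    else davies_bouldin(som$codebook, node_lab)
  }, numeric(1))

  k_sel <- k_range[which.min(db)]   # which.min takes the first (smallest k) on ties
  node_region <- cutree(hc, k = k_sel)
  labels <- rep(NA_integer_, nrow(comp))
  labels[keep] <- node_region[bmu]

  structure(
    list(
      som = som, hclust = hc,
      db_curve = tibble(k = k_range, db = db),
      k = k_sel, labels = labels, node_region = node_region, bmu = bmu,
      comp_meta = select(as_tibble(comp), "grid_id", "ix", "iy", "x_um", "y_um", "empty"),
      phenotypes = attr(comp, "phenotypes"),
      normalization = attr(comp, "normalization"),
      grid_dims = c(nx = attr(comp, "nx"), ny = attr(comp, "ny")),
      min_cells = min_cells,
      seed = seed
    ),
    class = "caf_region_model"
  )
}

#' @export
print.caf_region_model <- function(x, ...) {
  cat("<caf_region_model> ", x$k, " regions selected from k in {",
      paste(range(x$db_curve$k), collapse = "..."), "} by Davies-Bouldin (min = ",
      signif(min(x$db_curve$db), 4), ");\n  ",
      sum(!is.na(x$labels)), " neighborhoods labeled, ",
      sum(is.na(x$labels)), " background (empty or sparse).\n", sep = "")
  invisible(x)
}

#' @describeIn cluster_regions Per-neighborhood labels as a tibble
#'   (`grid_id`, `ix`, `iy`, `x_um`, `y_um`, `region`; empty neighborhoods
#'   have `NA` region).
#' @param x A `caf_region_model`.
#' @param ... Unused.
#' @export
tidy.caf_region_model <- function(x, ...) {
  mutate(x$comp_meta, region = x$labels)
}

#' @describeIn cluster_regions One-row model summary.
#' @export
glance.caf_region_model <- function(x, ...) {
  tibble(
    k = x$k,
    db = min(x$db_curve$db),
    n_neighborhoods = sum(!is.na(x$labels)),
    n_empty = sum(is.na(x$labels)),
    som_nodes = nrow(x$som$codebook),
    seed = x$seed
  )
}

#' Spatial region-label raster
#'
#' Reshapes a fitted model's neighborhood labels onto the raster lattice.
#'
#' @param model A `caf_region_model`.
#' @param grid The `caf_grid` the model's compositions were computed on
#'   (checked for size agreement); optional when the model carries its own
#'   lattice dimensions.
#' @return A `caf_region_raster`: integer matrix (ny rows x nx columns) of
#'   region labels with `NA` background, with the lattice geometry attached.
#' @export
region_map <- function(model, grid = NULL) {
  dims <- model$grid_dims
  if (!is.null(grid)) {
    if (grid_attr(grid, "nx") != dims["nx"] || grid_attr(grid, "ny") != dims["ny"]) {
      abort("`grid` lattice dimensions do not match the model's compositions.")
    }
  }
  m <- matrix(NA_integer_, nrow = dims["ny"], ncol = dims["nx"])
  m[cbind(model$comp_meta$iy, model$comp_meta$ix)] <- model$labels
  structure(m, k = model$k, class = "caf_region_raster")
}
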