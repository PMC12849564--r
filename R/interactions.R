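#' Boundary edges of a region label raster
#'
#' Enumerates all 8-connected (default) or 4-connected lattice pairs whose
#' region labels differ, counting each unordered pair of lattice points
#' once. Background (`NA`) neighborhoods never contribute edges.
#'
#' @param raster A `caf_region_raster` from [region_map()], or any integer
#'   matrix with `NA` background.
#' @param connectivity 8 or 4.
#' @return A tibble with one row per boundary edge: `iy_a`, `ix_a`, `iy_b`,
#'   `ix_b`, `label_a`, `label_b`.
#' @export
boundary_edges <- function(raster, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  m <- unclass(raster)
  if (!is.matrix(m)) abort("`raster` must be a matrix of region labels.")
  offsets <- list(c(0, 1), c(1, 0))
  if (connectivity == 8) offsets <- c(offsets, list(c(1, 1), c(1, -1)))
  ny <- nrow(m); nx <- ncol(m)
  out <- list()
  for (off in offsets) {
    dy <- off[1]; dx <- off[2]
    ys <- seq_len(ny - dy)
    xs <- if (dx >= 0) seq_len(nx - dx) else seq(1 - dx, nx)
    a <- m[ys, xs, drop = FALSE]
    b <- m[ys + dy, xs + dx, drop = FALSE]
    hit <- which(!is.na(a) & !is.na(b) & a != b, arr.ind = TRUE)
    if (nrow(hit)) {
      out[[length(out) + 1L]] <- tibble(
        iy_a = ys[hit[, 1]], ix_a = xs[hit[, 2]],
        iy_b = ys[hit[, 1]] + dy, ix_b = xs[hit[, 2]] + dx,
        label_a = a[hit], label_b = b[hit]
      )
    }
  }
  if (!length(out)) {
    return(tibble(iy_a = integer(), ix_a = integer(), iy_b = integer(),
                  ix_b = integer(), label_a = integer(), label_b = integer()))
  }
  bind_rows(out)
}

#' Directed shared-border percentage matrix
#'
#' `P[A, B]` is the percentage of region A's boundary edges that touch
#' region B: `100 * edges(A, B) / (all boundary edges incident to A)`. Rows
#' of regions with at least one boundary edge sum to 100.
#'
#' @param edges Edge table from [boundary_edges()].
#' @param labels Region labels to include (defaults to those present);
#'   regions with no boundary edges get a zero row and are flagged.
#' @return A `caf_interactions`: list with matrix `P` (percent), vector
#'   `flagged` (zero-border regions), `n_edges`.
#' @export
interaction_matrix <- function(edges, labels = NULL) {
  present <- sort(unique(c(edges$label_a, edges$label_b)))
  labels <- labels %||% present
  labels <- sort(unique(labels))
  k <- length(labels)
  P <- matrix(0, k, k, dimnames = list(labels, labels))
  counts <- matrix(0, k, k, dimnames = list(labels, labels))
  if (nrow(edges)) {
    both <- tibble(a = as.character(c(edges$label_a, edges$label_b)),
                   b = as.character(c(edges$label_b, edges$label_a)))
    tab <- count(both, .data$a, .data$b)
    counts[cbind(match(tab$a, labels), match(tab$b, labels))] <- tab$n
  }
  incident <- rowSums(counts)
  nz <- incident > 0
  P[nz, ] <- 100 * counts[nz, , drop = FALSE] / incident[nz]
  structure(
    list(P = P, counts = counts, flagged = labels[!nz], n_edges = nrow(edges)),
    class = "caf_interactions"
  )
}

#' @export
print.caf_interactions <- function(x, ...) {
  cat("<caf_interactions> ", nrow(x$P), " regions, ", x$n_edges, " boundary edges",
      if (length(x$flagged)) paste0("; flagged (no border): ",
                                    paste(x$flagged, collapse = ", ")),
      "\n", sep = "")
  print(round(x$P, 1))
  invisible(x)
}

#' @describeIn interaction_matrix Long-format edge percentages (`region_a`,
#'   `region_b`, `pct_ab`, `pct_ba`), one row per unordered pair.
#' @param x A `caf_interactions`.
#' @param ... Unused.
#' @export
tidy.caf_interactions <- function(x, ...) {
  labs <- rownames(x$P)
  k <- length(labs)
  if (k < 2) return(tibble(region_a = character(), region_b = character(),
                           pct_ab = numeric(), pct_ba = numeric()))
  idx <- which(upper.tri(x$P), arr.ind = TRUE)
  tibble(
    region_a = labs[idx[, 1]],
    region_b = labs[idx[, 2]],
    pct_ab = x$P[idx],
    pct_ba = x$P[idx[, c(2, 1), drop = FALSE]]
  )
}

#' Threshold the interaction matrix into a niche-adjacency graph
#'
#' Retains the undirected edge {A, B} when the shared-border percentage in
#' either direction reaches the cutoff (10% is the published default for
#' multiplex images, 5% for in-situ transcriptomics).
#'
#' @param interactions A `caf_interactions` (or bare percentage matrix).
#' @param cutoff Percent, in (0, 100].
#' @return An edge tibble: `region_a`, `region_b`, `pct_ab`, `pct_ba`,
#'   `retained`; retained edges form the region-interaction network.
#' @export
threshold_graph <- function(interactions, cutoff = 10) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 || cutoff > 100) {
    abort("`cutoff` must be a percentage in (0, 100].")
  }
  if (is.matrix(interactions)) {
    interactions <- structure(list(P = interactions, flagged = character(),
                                   n_edges = NA_integer_),
                              class = "caf_interactions")
  }
  tidy(interactions) |>
    mutate(retained = pmax(.data$pct_ab, .data$pct_ba) >= cutoff)
}

#' Average interaction matrices over samples
#'
#' Element-wise mean of per-sample shared-border percentage matrices on the
#' union of their label sets; a region absent from a sample contributes a
#' zero (flagged) row.
#'
#' @param interaction_list List of `caf_interactions`.
#' @return A `caf_interactions` with the averaged matrix; `flagged` lists
#'   regions missing or border-free in at least one sample.
#' @export
average_interactions <- function(interaction_list) {
  if (!length(interaction_list)) abort("Need at least one interaction matrix to average.")
  labels <- sort(unique(unlist(lapply(interaction_list, function(x) rownames(x$P)))))
  k <- length(labels)
  acc <- matrix(0, k, k, dimnames = list(labels, labels))
  flagged <- character()
  for (x in interaction_list) {
    cur <- matrix(0, k, k, dimnames = list(labels, labels))
    have <- rownames(x$P)
    cur[have, have] <- x$P
    flagged <- union(flagged, c(setdiff(labels, have), x$flagged))
    acc <- acc + cur
  }
  structure(
    list(P = acc / length(interaction_list), counts = NULL,
         flagged = sort(flagged), n_edges = NA_integer_,
         n_samples = length(interaction_list)),
    class = "caf_interactions"
  )
}
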