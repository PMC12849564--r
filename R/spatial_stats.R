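#' Pseudo-space ordering of neighborhoods
#'
#' Sorts neighborhoods along a one-dimensional composition axis and smooths
#' each phenotype's abundance along the ordering, visualizing gradients
#' between, e.g., immune-rich and tumor-rich ends of a tissue. The default
#' key is `immune fraction - tumor fraction`, descending (immune-rich
#' first); ties break by total cell count, then grid index, so the
#' ordering is invariant to the row order of the input.
#'
#' @param comp A fraction-normalized `caf_composition` (raw counts are
#'   normalized on the fly); empty neighborhoods are excluded.
#' @param key Either a character vector of two phenotype names
#'   `c(positive, negative)` giving the key `frac[positive] -
#'   frac[negative]`, or a function of the fraction tibble returning one
#'   numeric per row.
#' @param descending Sort direction; reversing the sign of the key and the
#'   direction gives the reversed permutation.
#' @param window Smoothing window as a fraction of the number of
#'   neighborhoods (centered moving average).
#' @return A `caf_pseudospace` tibble: `position` (1 = first in ordering),
#'   `grid_id`, `key`, raw fraction columns, and smoothed abundance columns
#'   `<phenotype>_smooth`.
#' @export
pseudospace <- function(comp, key = c("immune", "tumor"), descending = TRUE,
                        window = 0.05) {
  if (!inherits(comp, "caf_composition")) abort("`comp` must come from compute_neighborhoods().")
  comp <- normalize_composition(comp, "fraction")
  keep <- !comp$empty
  if (!any(keep)) abort("All neighborhoods are empty; nothing to order.")
  ph <- attr(comp, "phenotypes")
  fr <- as_tibble(comp[keep, , drop = FALSE])
  keyval <- if (is.function(key)) {
    key(fr[ph])
  } else {
    if (!all(key %in% ph)) abort("`key` phenotypes not present in the composition.")
    fr[[key[1]]] - fr[[key[2]]]
  }
  ord <- order(if (descending) -keyval else keyval, -fr$total, fr$grid_id)
  fr <- fr[ord, ]
  n <- nrow(fr)
  win <- max(3L, as.integer(round(window * n)))
  out <- tibble(position = seq_len(n), grid_id = fr$grid_id, key = keyval[ord])
  out <- bind_cols(out, fr[ph])
  for (p in ph) out[[paste0(p, "_smooth")]] <- rolling_mean(fr[[p]], win)
  structure(out, phenotypes = ph, window = win,
            class = c("caf_pseudospace", class(out)))
}

#' Nearest-target distances with censoring
#'
#' For every source cell, the Euclidean distance to the nearest target of
#' each requested class (immune cells, tumor cells, vessel tiles), computed
#' within the same sample. Distances beyond `censor_radius` are flagged
#' censored (not zero, not dropped from the table); per-sample means are
#' taken over uncensored values only. The published analysis reports means
#' within a 10 µm radius and inspects full distributions within 100 µm,
#' hence the two conventional radii.
#'
#' @param cells Phenotyped cell table.
#' @param source_phenotypes Phenotypes acting as sources (e.g. the CAF
#'   substates).
#' @param targets Subset of `c("immune", "tumor", "vessel")`.
#' @param tiles Vessel tile table (required for the `"vessel"` target); a
#'   `sample_id` column matches tiles to samples, otherwise all tiles are
#'   used for every sample.
#' @param censor_radius Censoring radius in µm.
#' @return A `caf_distances` tibble: `sample_id`, `cell_id`, `phenotype`,
#'   `target`, `distance_um`, `censored`.
#' @export
nearest_distances <- function(cells, source_phenotypes = c("mCAF1", "mCAF2", "vCAF1", "vCAF2"),
                              targets = c("immune", "tumor", "vessel"),
                              tiles = NULL, censor_radius = 10) {
  assert_cells(cells, phenotyped = TRUE)
  targets <- match.arg(targets, several.ok = TRUE)
  if ("vessel" %in% targets && is.null(tiles)) {
    abort('Target "vessel" requires a `tiles` table from tile_vessels().')
  }
  if (censor_radius <= 0) abort("`censor_radius` must be > 0.")
  res <- list()
  for (sid in unique(cells$sample_id)) {
    sub <- cells[cells$sample_id == sid, ]
    src <- sub[sub$phenotype %in% source_phenotypes, ]
    if (!nrow(src)) next
    for (tg in targets) {
      tp <- if (tg == "vessel") {
        tt <- tiles
        if ("sample_id" %in% names(tt)) tt <- tt[tt$sample_id == sid, ]
        cbind(tt$x_um, tt$y_um)
      } else {
        tcells <- sub[sub$phenotype == tg, ]
        cbind(tcells$x_um, tcells$y_um)
      }
      d <- censored_nn(cbind(src$x_um, src$y_um), tp, censor_radius)
      if (all(is.na(d))) {
        warn(paste0("Sample ", sid, ": no ", tg, " target within ", censor_radius,
                    " um of any source; all distances censored."))
      }
      res[[length(res) + 1L]] <- tibble(
        sample_id = sid, cell_id = src$cell_id, phenotype = src$phenotype,
        target = tg, distance_um = d, censored = is.na(d)
      )
    }
  }
  out <- bind_rows(res)
  structure(out, censor_radius = censor_radius,
            class = c("caf_distances", class(out)))
}

# nearest-neighbor distance from each source row to the target set, NA when
# no target lies within `radius`; bucket grid keeps the candidate set local
censored_nn <- function(src, tgt, radius) {
  ns <- nrow(src)
  if (ns == 0L) return(numeric(0))
  if (is.null(tgt) || nrow(tgt) == 0L) return(rep(NA_real_, ns))
  bx <- floor(tgt[, 1] / radius)
  by <- floor(tgt[, 2] / radius)
  key <- paste(bx, by)
  buckets <- split(seq_len(nrow(tgt)), key)
  sbx <- floor(src[, 1] / radius)
  sby <- floor(src[, 2] / radius)
  out <- rep(NA_real_, ns)
  for (i in seq_len(ns)) {
    keys <- paste(rep(sbx[i] + (-1:1), each = 3), sby[i] + (-1:1))
    cand <- unlist(buckets[keys], use.names = FALSE)
    if (!length(cand)) next
    d2 <- (tgt[cand, 1] - src[i, 1])^2 + (tgt[cand, 2] - src[i, 2])^2
    dmin <- sqrt(min(d2))
    if (dmin <= radius) out[i] <- dmin
  }
  out
}

#' Per-sample mean nearest distances
#'
#' @param distances A `caf_distances` table.
#' @return Tibble `sample_id`, `phenotype`, `target`, `n_uncensored`,
#'   `mean_distance_um` (NA when everything is censored).
#' @export
summarise_distances <- function(distances) {
  distances |>
    group_by(.data$sample_id, .data$phenotype, .data$target) |>
    summarise(
      n_uncensored = sum(!.data$censored),
      mean_distance_um = if (any(!.data$censored)) {
        mean(.data$distance_um[!.data$censored])
      } else NA_real_,
      .groups = "drop"
    )
}

#' Per-sample phenotype percentages
#'
#' Percentage of classified cells per phenotype and sample; unclassified
#' cells are excluded from the denominator. Samples without classified
#' cells are dropped with a warning.
#'
#' @param cells Phenotyped cell table with `sample_id` and `stage`.
#' @return Tibble `sample_id`, `stage`, `phenotype`, `n`, `percent` (sums
#'   to 100 per sample).
#' @export
composition_summary <- function(cells) {
  assert_cells(cells, phenotyped = TRUE)
  classified <- filter(cells, .data$phenotype != "unclassified")
  dropped <- setdiff(unique(cells$sample_id), unique(classified$sample_id))
  if (length(dropped)) {
    warn(paste0("Sample(s) without classified cells dropped: ",
                paste(dropped, collapse = ", ")))
  }
  classified |>
    group_by(.data$sample_id, .data$stage, .data$phenotype) |>
    summarise(n = n(), .groups = "drop_last") |>
    mutate(percent = 100 * .data$n / sum(.data$n)) |>
    ungroup()
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided rank-sum test (exact for small tie-free samples, normal
#' approximation with tie correction otherwise) with the significance-star
#' bands used in the figures: `*` p <= 0.05, `**` <= 0.01, `***` <= 0.001,
#' `****` <= 0.0001.
#'
#' @param a,b Numeric vectors of per-sample values.
#' @return A one-row tibble: `n_a`, `n_b`, `rank_sum_a` (rank sum of group
#'   a), `statistic` (Mann-Whitney U), `p_value`, `stars`.
#' @export
#' @examples
#' wilcoxon_compare(c(1, 2, 3), c(4, 5, 6))
wilcoxon_compare <- function(a, b) {
  if (!length(a) || !length(b)) abort("Both groups must contain at least one value.")
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  u <- unname(wt$statistic)
  tibble(
    n_a = length(a), n_b = length(b),
    rank_sum_a = u + length(a) * (length(a) + 1) / 2,
    statistic = u,
    p_value = wt$p.value,
    stars = p_stars(wt$p.value)
  )
}

p_stars <- function(p) {
  dplyr::case_when(
    p <= 1e-4 ~ "****",
    p <= 1e-3 ~ "***",
    p <= 1e-2 ~ "**",
    p <= 5e-2 ~ "*",
    TRUE ~ "ns"
  )
}
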