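#' Calibrate per-marker positivity thresholds
#'
#' Stands in for interactively trained per-marker classifiers: each marker
#' gets a single intensity threshold. The default method fits a 2-component
#' Gaussian mixture to log intensities (via \pkg{mclust}) and places the
#' threshold at the equal-posterior crossing between the two components,
#' solved in closed form. The alternative is a fixed quantile of the
#' intensity distribution.
#'
#' @param cells Cell table with one positive intensity column per marker.
#' @param markers Markers to calibrate; defaults to the panel minus DAPI.
#' @param method `"gmm"` or `"quantile"`.
#' @param quantile_q Quantile used by `method = "quantile"`.
#' @return A tibble with columns `marker`, `threshold` (intensity units),
#'   `method`.
#' @export
calibrate_thresholds <- function(cells, markers = setdiff(caf_markers(), "dapi"),
                                 method = c("gmm", "quantile"), quantile_q = 0.5) {
  method <- match.arg(method)
  assert_cells(cells, markers = markers)
  if (nrow(cells) < 100) abort("Threshold calibration needs at least 100 cells.")
  thr <- vapply(markers, function(mk) {
    v <- cells[[mk]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      abort(paste0("Marker `", mk, "` has non-positive or non-finite intensities."))
    }
    if (max(v) - min(v) < .Machine$double.eps * max(v)) {
      abort(paste0("Marker `", mk, "` intensity is constant; cannot calibrate a threshold."))
    }
    switch(method,
      gmm = gmm_threshold(log(v)),
      quantile = unname(quantile(v, quantile_q))
    )
  }, numeric(1))
  tibble(marker = markers, threshold = unname(thr), method = method)
}

# equal-posterior crossing of a 2-component univariate Gaussian mixture
# fitted to x (log intensities); returned on the intensity scale
gmm_threshold <- function(x) {
  mclustBIC <- mclust::mclustBIC  # Mclust() resolves this in the caller frame
  fit <- withr::with_seed(20260101L, {
    init <- if (length(x) > 5000) {
      list(subset = sample.int(length(x), 2000L))
    } else NULL
    mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE,
                   initialization = init)
  })
  if (is.null(fit)) abort("Mixture fit failed; marker distribution may be degenerate.")
  m <- fit$parameters$mean
  s <- sqrt(fit$parameters$variance$sigmasq)
  if (length(s) == 1L) s <- rep(s, 2)
  p <- fit$parameters$pro
  o <- order(m)
  m <- m[o]; s <- s[o]; p <- p[o]
  # p1 N(m1,s1) = p2 N(m2,s2)  <=>  A t^2 + B t + C = 0 on the log scale
  A <- 1 / (2 * s[2]^2) - 1 / (2 * s[1]^2)
  B <- m[1] / s[1]^2 - m[2] / s[2]^2
  C <- m[2]^2 / (2 * s[2]^2) - m[1]^2 / (2 * s[1]^2) + log((p[1] * s[2]) / (p[2] * s[1]))
  roots <- if (abs(A) < 1e-12) {
    -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) numeric(0) else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  inside <- roots[roots > m[1] & roots < m[2]]
  t_log <- if (length(inside)) inside[1] else (m[1] * s[2] + m[2] * s[1]) / (s[1] + s[2])
  exp(t_log)
}

#' The hierarchical gating scheme
#'
#' Marker-positivity patterns mapped to phenotype labels, applied in a fixed
#' order: MCAM and PDGFRa are evaluated jointly first (double-positive cells
#' become intermediate CAFs; single positives enter the vCAF or mCAF branch,
#' split into substate 1 vs 2 by aSMA); remaining cells are then tested
#' sequentially CD31 (endothelial), CD45 (immune), PanCK (tumor) and
#' finally aSMA alone (myofibroblast). Anything else is unclassified.
#'
#' @return A list describing the scheme (for the run-provenance record).
#' @export
default_scheme <- function() {
  list(
    joint = c("mcam", "pdgfra"),
    substate_marker = "asma",
    sequential = c(cd31 = "endothelial", cd45 = "immune", panck = "tumor"),
    fallback = c(asma = "myofibroblast"),
    labels = caf_phenotypes(include_unclassified = TRUE)
  )
}

#' Assign phenotypes by hierarchical sequential gating
#'
#' @param cells Cell table with the scheme's marker columns.
#' @param calls Threshold table from [calibrate_thresholds()].
#' @param scheme Gating scheme; see [default_scheme()].
#' @return `cells` with added columns `phenotype` and `classified`
#'   (logical; unclassified cells are flagged and are ignored by all
#'   downstream analyses).
#' @export
#' @examples
#' sim <- niche_architecture("late", seed = 1)
#' calls <- calibrate_thresholds(sim$cells)
#' cells <- classify_cells(sim$cells, calls)
#' table(cells$phenotype)
classify_cells <- function(cells, calls, scheme = default_scheme()) {
  need <- unique(c(scheme$joint, scheme$substate_marker,
                   names(scheme$sequential), names(scheme$fallback)))
  assert_cells(cells, markers = need)
  thr <- setNames(calls$threshold, calls$marker)
  miss <- setdiff(need, names(thr))
  if (length(miss)) abort(paste0("No calibrated threshold for marker(s): ",
                                 paste(miss, collapse = ", ")))
  pos <- lapply(need, function(mk) cells[[mk]] > thr[[mk]])
  names(pos) <- need

  n <- nrow(cells)
  label <- rep("unclassified", n)
  mcam <- pos[["mcam"]]; pdgfra <- pos[["pdgfra"]]; asma <- pos[[scheme$substate_marker]]
  label[mcam & pdgfra] <- "intCAF"
  label[pdgfra & !mcam] <- ifelse(asma[pdgfra & !mcam], "mCAF1", "mCAF2")
  label[mcam & !pdgfra] <- ifelse(asma[mcam & !pdgfra], "vCAF1", "vCAF2")
  free <- label == "unclassified"
  for (mk in names(scheme$sequential)) {
    hit <- free & pos[[mk]]
    label[hit] <- scheme$sequential[[mk]]
    free <- free & !hit
  }
  for (mk in names(scheme$fallback)) {
    hit <- free & pos[[mk]]
    label[hit] <- scheme$fallback[[mk]]
    free <- free & !hit
  }
  cells$phenotype <- label
  cells$classified <- label != "unclassified"
  cells
}

#' Per-sample mean marker intensity by phenotype
#'
#' @param cells Phenotyped cell table.
#' @param marker Marker column to summarise.
#' @return A tibble `sample_id`, `phenotype`, `n`, `mean_intensity`, one row
#'   per (sample, phenotype) with at least one classified cell; missing
#'   combinations are omitted with a warning.
#' @export
intensity_by_phenotype <- function(cells, marker) {
  assert_cells(cells, markers = marker, phenotyped = TRUE)
  classified <- filter(cells, .data$phenotype != "unclassified")
  out <- classified |>
    group_by(.data$sample_id, .data$phenotype) |>
    summarise(n = n(), mean_intensity = mean(.data[[marker]]), .groups = "drop")
  full <- tidyr::expand_grid(
    sample_id = unique(classified$sample_id),
    phenotype = unique(classified$phenotype)
  )
  missing <- dplyr::anti_join(full, out, by = c("sample_id", "phenotype"))
  if (nrow(missing)) {
    warn(paste0(nrow(missing), " (sample, phenotype) combination(s) have no cells ",
                "and were omitted, e.g. ", missing$sample_id[1], "/", missing$phenotype[1]))
  }
  out
}
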