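# shared fixtures, built once per test run and memoised

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# a small phenotyped late-stage sample shared by several test files
small_sample <- function() {
  memo("small_sample", {
    sim <- niche_architecture("late", seed = 7L)
    calls <- calibrate_thresholds(sim$cells)
    cells <- classify_cells(sim$cells, calls)
    list(sim = sim, calls = calls, cells = cells)
  })
}

# cells with exactly one marker positive, for gating-logic tests:
# build intensities directly from a positivity pattern
cells_from_pattern <- function(patterns, pos = 100, neg = 1) {
  mk <- caf_markers()
  rows <- lapply(seq_along(patterns), function(i) {
    v <- setNames(rep(neg, length(mk)), mk)
    v[patterns[[i]]] <- pos
    v["dapi"] <- pos
    v
  })
  m <- do.call(rbind, rows)
  out <- tibble::tibble(
    cell_id = as.character(seq_along(patterns)),
    sample_id = "t",
    stage = "late",
    x_um = seq_along(patterns) * 10,
    y_um = 0
  )
  dplyr::bind_cols(out, tibble::as_tibble(m))
}

flat_calls <- function(threshold = 10) {
  tibble::tibble(
    marker = setdiff(caf_markers(), "dapi"),
    threshold = threshold,
    method = "fixed"
  )
}

# star-convex "blob" polygon used by tiling tests
blob_polygon <- function(seed = 1, n = 24, r_mean = 60, r_sd = 18,
                         center = c(100, 100)) {
  withr::with_seed(seed, {
    ang <- sort(runif(n, 0, 2 * pi))
    rad <- pmax(abs(rnorm(n, r_mean, r_sd)), 12)
    cbind(center[1] + rad * cos(ang), center[2] + rad * sin(ang))
  })
}

# area of a polygon by fine-grid rasterization (independent oracle)
raster_area <- function(poly, step = 0.25) {
  xs <- seq(min(poly[, 1]), max(poly[, 1]), by = step)
  ys <- seq(min(poly[, 2]), max(poly[, 2]), by = step)
  g <- expand.grid(x = xs, y = ys)
  mean_inside <- mean(cafniche:::points_in_polygon(g$x, g$y, poly))
  mean_inside * (max(poly[, 1]) - min(poly[, 1])) * (max(poly[, 2]) - min(poly[, 2]))
}

# exact two-sided rank-sum p by exhaustive enumeration (independent oracle)
enum_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  ranks <- rank(pooled)
  obs <- sum(ranks[seq_along(a)])
  idx <- utils::combn(n, length(a))
  sums <- apply(idx, 2, function(i) sum(ranks[i]))
  mu <- length(a) * (n + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}
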