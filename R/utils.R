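# internal validation and small numeric helpers

assert_cells <- function(cells, markers = NULL, phenotyped = FALSE, call = rlang::caller_env()) {
  if (!is.data.frame(cells)) {
    abort("`cells` must be a data frame (one row per segmented cell).", call = call)
  }
  needed <- c("x_um", "y_um")
  missing <- setdiff(needed, names(cells))
  if (length(missing)) {
    abort(paste0("`cells` is missing coordinate column(s): ",
                 paste(missing, collapse = ", "),
                 ". Expected micrometre centroids `x_um`, `y_um`."), call = call)
  }
  if (!all(is.finite(cells$x_um)) || !all(is.finite(cells$y_um))) {
    abort("Cell coordinates contain non-finite values.", call = call)
  }
  if (!is.null(markers)) {
    miss <- setdiff(markers, names(cells))
    if (length(miss)) {
      abort(paste0("`cells` is missing marker column(s): ", paste(miss, collapse = ", ")),
            call = call)
    }
  }
  if (phenotyped && !"phenotype" %in% names(cells)) {
    abort("`cells` has no `phenotype` column; run `classify_cells()` first.", call = call)
  }
  invisible(cells)
}

# Euclidean distance matrix between rows of two matrices (n x d, m x d)
cross_dist2 <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# deterministic child seed; keeps within 32-bit signed range
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 1009) %% 2147483647L)
}

# centered moving average with shrinking windows at the edges
rolling_mean <- function(x, window) {
  n <- length(x)
  window <- max(1L, as.integer(window))
  half <- window %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
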