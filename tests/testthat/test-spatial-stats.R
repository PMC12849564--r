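tiny_comp <- function(rows) {
  # rows: list of named count vectors; cell groups sit exactly on lattice
  # points (radius = spacing = 100 puts the padded lattice through the cells)
  cells <- list()
  for (i in seq_along(rows)) {
    for (ph in names(rows[[i]])) {
      n <- rows[[i]][[ph]]
      if (n > 0) {
        cells[[length(cells) + 1L]] <- tibble::tibble(
          cell_id = paste0(i, "_", ph, "_", seq_len(n)), sample_id = "s",
          stage = "late", x_um = (i - 1) * 2000, y_um = 0,
          phenotype = ph, classified = TRUE
        )
      }
    }
  }
  cells <- dplyr::bind_rows(cells)
  compute_neighborhoods(cells, make_grid(cells, spacing = 100, radius = 100))
}

test_that("pseudo-space sorts immune-rich neighborhoods first; reversing the sort flips it", {
  comp <- tiny_comp(list(c(immune = 1, tumor = 9), c(immune = 9, tumor = 1)))
  ps <- pseudospace(comp)
  expect_equal(ps$immune[1], 0.9)
  expect_equal(ps$immune[nrow(ps)], 0.1)
  expect_equal(ps$key, sort(ps$key, decreasing = TRUE))
  rev_ps <- pseudospace(comp, descending = FALSE)
  expect_equal(rev_ps$immune[1], 0.1)
  expect_equal(rev_ps$key, sort(rev_ps$key))
})

test_that("pseudo-space is invariant to input row order", {
  sm <- small_sample()
  comp <- memo("late7_comp", normalize_composition(
    compute_neighborhoods(sm$cells, make_grid(sm$cells)), "fraction"))
  ps1 <- pseudospace(comp)
  perm <- withr::with_seed(8L, sample(nrow(comp)))
  comp_shuffled <- comp[perm, ]
  attributes(comp_shuffled) <- utils::modifyList(
    attributes(comp_shuffled),
    attributes(comp)[c("phenotypes", "normalization", "spacing", "radius",
                       "nx", "ny", "origin", "class")])
  ps2 <- pseudospace(comp_shuffled)
  expect_equal(ps1$grid_id, ps2$grid_id)
  expect_equal(ps1$immune_smooth, ps2$immune_smooth)
})

test_that("pseudo-space recovers the planted late-stage CAF gradient", {
  sm <- small_sample()
  comp <- memo("late7_comp", normalize_composition(
    compute_neighborhoods(sm$cells, make_grid(sm$cells)), "fraction"))
  ps <- pseudospace(comp)
  dec <- ceiling(nrow(ps) / 10)
  immune_end <- ps[seq_len(dec), ]
  tumor_end <- ps[seq(nrow(ps) - dec + 1, nrow(ps)), ]
  expect_gt(mean(immune_end$mCAF2), mean(immune_end$mCAF1))
  expect_gt(mean(tumor_end$mCAF1), mean(tumor_end$mCAF2))
  expect_error(pseudospace(comp, key = c("immune", "nothere")), "not present")
})

test_that("nearest distances censor correctly and match brute force", {
  src <- tibble::tibble(
    cell_id = c("a", "b"), sample_id = "s", stage = "late",
    x_um = c(0, 100), y_um = c(0, 0),
    phenotype = c("mCAF1", "mCAF1"), classified = TRUE
  )
  tiles <- tibble::tibble(vessel_id = 1L, tile_id = c("t1", "t2"),
                          x_um = c(3, 112), y_um = c(4, 0), area_um2 = 100)
  d <- nearest_distances(src, targets = "vessel", tiles = tiles, censor_radius = 10)
  expect_equal(d$distance_um[d$cell_id == "a"], 5)          # 3-4-5 triangle
  expect_true(d$censored[d$cell_id == "b"])                 # nearest at 12 > 10
  expect_true(is.na(d$distance_um[d$cell_id == "b"]))

  withr::with_seed(20L, {
    cells <- tibble::tibble(
      cell_id = as.character(1:200), sample_id = "s", stage = "late",
      x_um = runif(200, 0, 400), y_um = runif(200, 0, 400),
      phenotype = sample(c("mCAF1", "vCAF1", "immune", "tumor"), 200, TRUE),
      classified = TRUE
    )
  })
  d <- nearest_distances(cells, source_phenotypes = c("mCAF1", "vCAF1"),
                         targets = c("immune", "tumor"), censor_radius = 150)
  for (i in seq_len(nrow(d))) {
    row <- d[i, ]
    src_xy <- cells[cells$cell_id == row$cell_id, ]
    tg <- cells[cells$phenotype == row$target, ]
    bf <- sqrt(min((tg$x_um - src_xy$x_um)^2 + (tg$y_um - src_xy$y_um)^2))
    if (bf <= 150) expect_equal(row$distance_um, bf) else expect_true(row$censored)
  }
})

test_that("a sample without targets is all-censored with a warning", {
  src <- tibble::tibble(cell_id = "a", sample_id = "s", stage = "late",
                        x_um = 0, y_um = 0, phenotype = "mCAF1", classified = TRUE)
  expect_warning(d <- nearest_distances(src, targets = "tumor", censor_radius = 10),
                 "censored")
  expect_true(all(d$censored))
  expect_error(nearest_distances(src, targets = "vessel"), "tiles")
})

test_that("composition summaries are per-sample percentages of classified cells", {
  cells <- cells_from_pattern(list("panck", "panck", "cd45", c("pdgfra", "asma"),
                                   character(0)))
  cells <- classify_cells(cells, flat_calls())
  cs <- composition_summary(cells)
  expect_equal(cs$percent[cs$phenotype == "tumor"], 50)
  expect_equal(cs$percent[cs$phenotype == "immune"], 25)
  expect_equal(cs$percent[cs$phenotype == "mCAF1"], 25)
  expect_equal(sum(cs$percent), 100)
})

test_that("the planted early-to-late immune increase is recovered", {
  pct <- function(stage, seed) {
    coh <- simulate_cohort(stage, 5, seed = seed)
    cells <- coh$cells
    cells$phenotype <- cells$true_phenotype
    cells$classified <- TRUE
    cs <- composition_summary(cells)
    cs$percent[cs$phenotype == "immune"]
  }
  early <- pct("early", 51L)
  late <- pct("late", 52L)
  cmp <- wilcoxon_compare(late, early)
  expect_gt(median(late), median(early))
  expect_lte(cmp$p_value, 0.05)
})

test_that("wilcoxon_compare reproduces the exact small-sample distribution", {
  res <- wilcoxon_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$rank_sum_a, 6)       # minimum possible rank sum
  expect_equal(res$p_value, 0.1)        # 2/20 assignments as extreme

  same <- wilcoxon_compare(c(1, 2, 5), c(1, 2, 5))
  expect_gt(same$p_value, 0.99)

  a <- c(1.2, 3.4, 0.7); b <- c(2.2, 5.5, 8.1, 0.4)
  expect_equal(wilcoxon_compare(a, b)$p_value, wilcoxon_compare(10 * a, 10 * b)$p_value)
  expect_equal(wilcoxon_compare(a, b)$statistic, wilcoxon_compare(10 * a, 10 * b)$statistic)

  # exhaustive-enumeration oracle for all tie-free cases with n_total <= 10
  withr::with_seed(33L, {
    for (rep in 1:10) {
      na <- sample(1:5, 1); nb <- sample(1:5, 1)
      a <- round(rnorm(na), 6); b <- round(rnorm(nb) + 0.5, 6)
      expect_equal(wilcoxon_compare(a, b)$p_value, enum_wilcox_p(a, b),
                   tolerance = 1e-12)
    }
  })
  expect_error(wilcoxon_compare(numeric(0), 1), "at least one")
})

test_that("significance stars follow the figure-legend bands", {
  expect_equal(cafniche:::p_stars(c(0.2, 0.05, 0.01, 0.001, 0.0001)),
               c("ns", "*", "**", "***", "****"))
})
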