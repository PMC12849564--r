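# second, independent Davies-Bouldin implementation (textbook formula)
db_reference <- function(x, labels) {
  lv <- sort(unique(labels))
  cent <- t(sapply(lv, function(l) colMeans(x[labels == l, , drop = FALSE])))
  s <- sapply(seq_along(lv), function(i) {
    rows <- x[labels == lv[i], , drop = FALSE]
    mean(sqrt(colSums((t(rows) - cent[i, ])^2)))
  })
  total <- 0
  for (i in seq_along(lv)) {
    best <- -Inf
    for (j in seq_along(lv)) {
      if (i == j) next
      dij <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      best <- max(best, (s[i] + s[j]) / dij)
    }
    total <- total + best
  }
  total / length(lv)
}

test_that("the hand-computed two-cluster example gives DB = 0.2", {
  # two clusters, centroids 10 apart, mean dispersion exactly 1 each
  x <- rbind(c(-1, 0), c(1, 0), c(9, 0), c(11, 0))
  expect_equal(davies_bouldin(x, c(1, 1, 2, 2)), 0.2, tolerance = 1e-12)
})

test_that("DB matches an independent reimplementation on random labelings", {
  withr::with_seed(42L, {
    for (rep in 1:8) {
      n <- sample(30:80, 1)
      x <- matrix(rnorm(n * 4), ncol = 4)
      labels <- sample(1:sample(2:5, 1), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      expect_equal(davies_bouldin(x, labels), db_reference(x, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("DB is invariant to duplication and decreases with separation", {
  withr::with_seed(7L, {
    x <- rbind(matrix(rnorm(60), ncol = 2), matrix(rnorm(60, mean = 6), ncol = 2))
  })
  lab <- rep(1:2, each = 30)
  expect_equal(davies_bouldin(rbind(x, x), c(lab, lab)), davies_bouldin(x, lab),
               tolerance = 1e-12)
  x_far <- x
  x_far[lab == 2, ] <- x_far[lab == 2, ] + 10
  expect_lt(davies_bouldin(x_far, lab), davies_bouldin(x, lab))
  expect_error(davies_bouldin(x, rep(1, nrow(x))), "2 clusters")
  expect_error(davies_bouldin(rbind(c(0, 0), c(0, 0)), c(1, 2)), "[Cc]oincident")
})

test_that("a 2x1 SOM places one node per well-separated mass", {
  withr::with_seed(3L, {
    a <- matrix(rnorm(200, 0, 0.2), ncol = 2)
    b <- matrix(rnorm(200, 8, 0.2), ncol = 2)
  })
  x <- rbind(a, b)
  som <- fit_som(x, grid_shape = c(2, 1), iterations = 40, seed = 1L)
  # undo scaling to compare against the mass centroids (k-means oracle)
  cb <- sweep(sweep(som$codebook, 2, som$scale, "*"), 2, som$center, "+")
  km <- kmeans(x, 2, nstart = 5)
  ord_cb <- order(cb[, 1])
  ord_km <- order(km$centers[, 1])
  expect_equal(unname(cb[ord_cb, ]), unname(km$centers[ord_km, ]), tolerance = 0.05)
})

test_that("SOM training is deterministic and handles degenerate data", {
  withr::with_seed(2L, x <- matrix(rnorm(500), ncol = 5))
  s1 <- fit_som(x, grid_shape = c(4, 4), seed = 9L)
  s2 <- fit_som(x, grid_shape = c(4, 4), seed = 9L)
  expect_identical(s1$codebook, s2$codebook)

  same <- matrix(rep(c(1, 2, 3), each = 50), ncol = 3)
  som <- fit_som(same, grid_shape = c(2, 2), seed = 1L)
  # all nodes collapse to the (scaled) single observation: zero vector
  expect_true(all(abs(som$codebook) < 1e-9))

  expect_error(fit_som(x[1:10, ], grid_shape = c(10, 10)), "smaller")
})

test_that("cluster_regions recovers a planted three-archetype layout", {
  ph <- caf_phenotypes()
  three_layout <- cafniche:::new_layout(
    field = c(1500, 1500),
    region_at = function(x, y) c("A", "B", "C")[pmin(floor(x / 500) + 1L, 3L)],
    region_names = c("A", "B", "C"),
    adjacency = tibble::tibble(a = c("A", "B"), b = c("B", "C")),
    vessel_plan = NULL
  )
  arch <- dplyr::bind_rows(
    tibble::tibble(name = "A", role = "tumor_core", density = 6000),
    tibble::tibble(name = "B", role = "immune", density = 6000),
    tibble::tibble(name = "C", role = "mcaf2", density = 6000)
  )
  # every phenotype varies across the three archetypes, so no feature is
  # reduced to standardized Poisson noise by the z-scaling
  frac <- rbind(
    c(.50, .02, .03, .15, .02, .10, .02, .06, .10),
    c(.02, .50, .10, .02, .12, .02, .12, .02, .08),
    c(.05, .05, .03, .08, .50, .05, .04, .12, .08)
  )
  colnames(frac) <- ph
  arch <- dplyr::bind_cols(arch, tibble::as_tibble(frac))

  hits <- 0L
  for (s in 1:6) {
    sim <- generate_tissue(three_layout, arch, seed = s, stage = "late")
    cells <- sim$cells
    cells$phenotype <- cells$true_phenotype
    cells$classified <- TRUE
    comp <- normalize_composition(
      compute_neighborhoods(cells, make_grid(cells)), "fraction")
    model <- cluster_regions(comp, k_range = 2:6, som_shape = c(6, 6), seed = s)
    hits <- hits + (model$k == 3L)
  }
  expect_gte(hits, 5L)
})

test_that("cluster_regions respects a forced k and labels every kept neighborhood", {
  sm <- small_sample()
  comp <- memo("late7_comp", normalize_composition(
    compute_neighborhoods(sm$cells, make_grid(sm$cells)), "fraction"))
  model <- memo("late7_model", cluster_regions(comp, seed = 7L))
  forced <- cluster_regions(comp, k_range = 2, som_shape = c(4, 4),
                            iterations = 20, seed = 1L)
  expect_equal(forced$k, 2L)
  expect_true(all(!is.na(model$labels[!comp$empty & comp$total >= model$min_cells])))
  expect_true(all(model$labels[!is.na(model$labels)] %in% seq_len(model$k)))
  expect_error(cluster_regions(comp, k_range = integer(0)), "empty")
  expect_error(cluster_regions(comp, k_range = 1:3), "within")
})

test_that("tidy/glance/region_map expose the fitted model coherently", {
  sm <- small_sample()
  comp <- memo("late7_comp", normalize_composition(
    compute_neighborhoods(sm$cells, make_grid(sm$cells)), "fraction"))
  model <- memo("late7_model", cluster_regions(comp, seed = 7L))
  td <- tidy(model)
  expect_equal(nrow(td), nrow(comp))
  gl <- glance(model)
  expect_equal(gl$k, model$k)
  raster <- region_map(model)
  expect_equal(dim(raster), unname(c(attr(comp, "ny"), attr(comp, "nx"))))
  expect_setequal(unique(na.omit(as.vector(unclass(raster)))), seq_len(model$k))
  # round trip through the JSON container
  tmp <- tempfile(fileext = ".json")
  write_region_model(model, tmp)
  back <- read_region_model(tmp)
  expect_equal(back$k, model$k)
  expect_equal(back$labels, model$labels)
  expect_equal(back$som$codebook, model$som$codebook, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("region recovery on the planted architecture reaches ARI >= 0.8", {
  aris <- vapply(c(7L, 8L, 9L), function(s) {
    sim <- niche_architecture("late", seed = s)
    cells <- sim$cells
    cells$phenotype <- cells$true_phenotype
    cells$classified <- TRUE
    comp <- normalize_composition(
      compute_neighborhoods(cells, make_grid(cells)), "fraction")
    model <- cluster_regions(comp, seed = s)
    keep <- !is.na(model$labels)
    truth <- sim$truth$region_at(comp$x_um[keep], comp$y_um[keep])
    mclust::adjustedRandIndex(model$labels[keep], truth)
  }, numeric(1))
  expect_gte(median(aris), 0.8)
})
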