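one_region_archetype <- function(name = "A", density = 1000,
                                 comp = c(tumor = 1)) {
  ph <- caf_phenotypes()
  frac <- setNames(rep(0, length(ph)), ph)
  frac[names(comp)] <- comp
  dplyr::bind_cols(
    tibble::tibble(name = name, role = "tumor_core", density = density),
    tibble::as_tibble(as.list(frac))
  )
}

test_that("cell counts follow the planted Poisson intensity", {
  lay <- layout_single("A", field = c(1000, 1000))
  arch <- one_region_archetype(density = 1000)
  sim <- generate_tissue(lay, arch, seed = 11L)
  # expected count 1000, Poisson sd ~ 31.6; 4 sigma band
  expect_gt(nrow(sim$cells), 1000 - 4 * sqrt(1000))
  expect_lt(nrow(sim$cells), 1000 + 4 * sqrt(1000))
})

test_that("generation is deterministic under a fixed seed and varies across seeds", {
  lay <- layout_single("A", field = c(500, 500))
  arch <- one_region_archetype(density = 2000, comp = c(tumor = 0.5, immune = 0.5))
  s1 <- generate_tissue(lay, arch, seed = 3L)
  s2 <- generate_tissue(lay, arch, seed = 3L)
  s3 <- generate_tissue(lay, arch, seed = 4L)
  expect_identical(s1$cells, s2$cells)
  expect_false(isTRUE(all.equal(nrow(s1$cells), nrow(s3$cells))) &&
                 isTRUE(all.equal(s1$cells$x_um[1], s3$cells$x_um[1])))
})

test_that("a degenerate composition yields a single phenotype", {
  lay <- layout_single("A", field = c(500, 500))
  sim <- generate_tissue(lay, one_region_archetype(density = 2000), seed = 5L)
  expect_true(all(sim$cells$true_phenotype == "tumor"))
})

test_that("realized region compositions converge to the planted fractions with density", {
  dev_at <- function(factor) {
    sim <- niche_architecture("late", seed = 21L, density_factor = factor)
    arch <- sim$truth$archetypes
    realized <- prop.table(table(sim$cells$true_region, sim$cells$true_phenotype), 1)
    planted <- as.matrix(arch[caf_phenotypes()])
    rownames(planted) <- arch$name
    mean(abs(realized[rownames(planted), colnames(planted)] - planted))
  }
  # vCAF relocation slightly perturbs fractions; deviation must still shrink
  expect_lt(dev_at(2), dev_at(0.2))
})

test_that("planted positive and negative intensity distributions are separable", {
  model <- default_intensity_model()
  q <- function(meanlog, sdlog, p) exp(meanlog + sdlog * qnorm(p))
  for (mk in setdiff(caf_markers(), "dapi")) {
    sub <- model[model$marker == mk, ]
    pos <- sub[sub$positive, ]
    neg <- sub[!sub$positive, ]
    # IQRs must not overlap: lowest positive 25th above highest negative 75th
    expect_gt(min(q(pos$meanlog, pos$sdlog, 0.25)),
              max(q(neg$meanlog, neg$sdlog, 0.75)), label = mk)
  }
  expect_error(default_intensity_model(pos_mean = 3, neg_mean = 4), "exceed")
})

test_that("the staged niche architecture plants the reported topology and region counts", {
  e <- niche_architecture("early", seed = 1L)
  expect_equal(e$truth$k_true, 9L)
  l <- niche_architecture("late", seed = 1L)
  expect_equal(l$truth$k_true, 7L)

  adj <- l$truth$adjacency
  has_edge <- function(adj, a, b) {
    any((adj$a == a & adj$b == b) | (adj$a == b & adj$b == a))
  }
  expect_true(has_edge(adj, "L6", "L1"))      # shield touches the core
  immune_regions <- c("L2", "L3", "L5")
  tumor_regions <- c("L1", "L6", "L7")
  for (i in immune_regions) for (t in tumor_regions) {
    expect_false(has_edge(adj, i, t))
  }

  # tumor core has the highest planted tumor fraction at both stages
  for (sim in list(e, l)) {
    arch <- sim$truth$archetypes
    expect_equal(arch$name[which.max(arch$tumor)],
                 arch$name[arch$role == "tumor_core"])
  }
})

test_that("the planted adjacency matches the realized geometry", {
  # rasterize the layout and enumerate the true region borders
  for (stage in c("early", "late")) {
    lay <- niche_layout(stage)
    g <- expand.grid(x = seq(5, 2995, by = 10), y = seq(5, 2995, by = 10))
    lab <- matrix(match(lay$region_at(g$x, g$y), lay$region_names),
                  nrow = length(unique(g$y)), byrow = TRUE)
    edges <- boundary_edges(lab)
    seen <- unique(tibble::tibble(
      a = lay$region_names[pmin(edges$label_a, edges$label_b)],
      b = lay$region_names[pmax(edges$label_a, edges$label_b)]
    ))
    planted <- unique(tibble::tibble(
      a = pmin(lay$adjacency$a, lay$adjacency$b),
      b = pmax(lay$adjacency$a, lay$adjacency$b)
    ))
    # every realized border was planted, and vice versa
    expect_setequal(paste(seen$a, seen$b), paste(planted$a, planted$b))
  }
})

test_that("vascular CAFs are planted closer to vessels than matrix CAFs", {
  sim <- niche_architecture("late", seed = 13L)
  tiles <- tile_vessels(sim$vessels)
  cells <- sim$cells
  cells$phenotype <- cells$true_phenotype
  d <- nearest_distances(cells, targets = "vessel", tiles = tiles,
                         censor_radius = 100)
  sm <- summarise_distances(d)
  vc <- mean(sm$mean_distance_um[sm$phenotype %in% c("vCAF1", "vCAF2")])
  mc <- mean(sm$mean_distance_um[sm$phenotype %in% c("mCAF1", "mCAF2")])
  expect_lt(vc, mc)
})

test_that("cohort simulation stacks samples with distinct ids and truths", {
  coh <- simulate_cohort("early", 3, seed = 2L)
  expect_equal(length(unique(coh$cells$sample_id)), 3)
  expect_equal(length(coh$truths), 3)
  expect_true(all(coh$cells$stage == "early"))
})
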