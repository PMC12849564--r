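#' Default marker-intensity model
#'
#' Per (phenotype, marker) pair: positivity status and a log-normal
#' distribution for the per-cell mean fluorescence intensity. Positive
#' markers are drawn around a location of `pos_mean` (arbitrary intensity
#' units), negatives around `neg_mean`; log-scale spread `sdlog` is common.
#' Log-normal is used because mean fluorescence intensities are strictly
#' positive and right-skewed. With the defaults, positive and negative
#' interquartile ranges are separated by several log-standard deviations,
#' so the planted phenotypes are recoverable by thresholding.
#'
#' @param pos_mean,neg_mean Median intensity of positive/negative cells.
#' @param sdlog Log-scale standard deviation.
#' @return A tibble with columns `phenotype`, `marker`, `positive`,
#'   `meanlog`, `sdlog`.
#' @export
default_intensity_model <- function(pos_mean = 60, neg_mean = 4, sdlog = 0.35) {
  if (pos_mean <= neg_mean) abort("`pos_mean` must exceed `neg_mean` (planted separability).")
  pos <- list(
    tumor = "panck", immune = "cd45", endothelial = "cd31",
    mCAF1 = c("pdgfra", "asma"), mCAF2 = "pdgfra",
    vCAF1 = c("mcam", "asma"), vCAF2 = "mcam",
    intCAF = c("mcam", "pdgfra"), myofibroblast = "asma"
  )
  grid <- tidyr::expand_grid(phenotype = caf_phenotypes(), marker = caf_markers())
  grid$positive <- mapply(function(ph, mk) {
    mk == "dapi" || mk %in% pos[[ph]]
  }, grid$phenotype, grid$marker)
  grid$meanlog <- ifelse(grid$positive, log(pos_mean), log(neg_mean))
  grid$sdlog <- sdlog
  validate_intensity_model(grid)
  grid
}

#' Validate an intensity model
#'
#' Requires, for every marker with both positive and negative phenotypes,
#' that every positive location strictly exceeds every negative location.
#'
#' @param model Tibble as from [default_intensity_model()].
#' @return The model, invisibly.
#' @export
validate_intensity_model <- function(model) {
  need <- c("phenotype", "marker", "positive", "meanlog", "sdlog")
  miss <- setdiff(need, names(model))
  if (length(miss)) abort(paste0("Intensity model missing column(s): ", paste(miss, collapse = ", ")))
  bad <- model |>
    group_by(.data$marker) |>
    summarise(
      sep = {
        p <- .data$meanlog[.data$positive]; q <- .data$meanlog[!.data$positive]
        length(p) == 0 || length(q) == 0 || min(p) > max(q)
      },
      .groups = "drop"
    ) |>
    filter(!.data$sep)
  if (nrow(bad)) {
    abort(paste0("Positive location must exceed negative location for marker(s): ",
                 paste(bad$marker, collapse = ", ")))
  }
  invisible(model)
}

new_layout <- function(field, region_at, region_names, adjacency, vessel_plan,
                       stage = NA_character_) {
  structure(
    list(field = field, region_at = region_at, region_names = region_names,
         adjacency = adjacency, vessel_plan = vessel_plan, stage = stage),
    class = "caf_layout"
  )
}

#' Single-region layout
#'
#' A rectangular field filled by one archetype; mainly useful for testing
#' count statistics of the point process.
#'
#' @param name Archetype name filling the field.
#' @param field Field size in µm, `c(width, height)`.
#' @param vessel_plan Optional vessel plan (see [niche_layout()]); default none.
#' @return A `caf_layout`.
#' @export
layout_single <- function(name, field = c(1000, 1000), vessel_plan = NULL) {
  new_layout(
    field = field,
    region_at = function(x, y) rep(name, length(x)),
    region_names = name,
    adjacency = tibble(a = character(), b = character()),
    vessel_plan = vessel_plan
  )
}

# default synthetic vessel plan; weights are relative acceptance
# probabilities for vessel centers by archetype role (tumor cores are
# nearly avascular, endothelial-enriched regions vessel-rich)
default_vessel_plan <- function(n = 45) {
  list(
    n = n,
    length_range = c(80, 220),
    width_range = c(12, 24),
    role_weights = c(endothelial = 1, endothelial2 = 1, tumor_core = 0.02),
    default_weight = 0.08,
    endothelial_per_um2 = 0.0005,
    perivascular = list(
      vCAF1 = list(prob = 0.8, decay = 5),
      vCAF2 = list(prob = 0.6, decay = 10)
    ),
    max_offset = 20,     # µm; enrichment limited to this distance from the wall
    search_radius = 75   # µm; vCAFs farther than this from any vessel stay put
                         # (keeps enrichment local so region compositions at the
                         # neighborhood scale are preserved)
  )
}

#' Procedural layout of the planted niche architecture
#'
#' Encodes the qualitative topology reported for the two tumor stages as an
#' explicit geometry on a 3 x 3 mm field: a concentric tumor nest
#' (core, mid, myofibroblastic-CAF shield ring) wrapped by an
#' endothelial-enriched ring, plus a second smaller tumor nest, with the
#' remaining stroma split into vertical stripes of immune-exclusive, mixed
#' immune+mCAF2 and mCAF2-exclusive archetypes. The endothelial ring keeps
#' immune and mCAF2 regions from ever bordering a tumor-enriched region,
#' while the shield ring directly borders the core. The early-stage layout
#' additionally plants the myofibroblast-exclusive region and a second
#' endothelial-enriched region as discs in the stromal zone.
#'
#' @param stage `"early"` or `"late"`.
#' @param field Field size in µm.
#' @param vessel_plan Vessel plan; see [default_vessel_plan()].
#' @return A `caf_layout` whose `adjacency` records the planted
#'   region-border plan.
#' @export
niche_layout <- function(stage = c("early", "late"), field = c(3000, 3000),
                         vessel_plan = default_vessel_plan()) {
  stage <- match.arg(stage)
  band_of <- function(x, y, labels, width = 1000) {
    idx <- pmin(pmax(floor(x / width) + 1L, 1L), length(labels))
    labels[idx]
  }
  if (stage == "late") {
    # one concentric tumor nest: core, mid-annulus split into a tumor-mid
    # sector and the mCAF1 shield sector (both touch the core), and an
    # endothelial buffer ring that insulates the stripes from tumor regions
    nest <- list(cx = 1500, cy = 1050, radii = c(450, 900, 1150),
                 labels = c("L1", "L6", "L4"),
                 sector = list(ring = 2L, from = 0, to = 2.4, label = "L7"))
    discs <- list()
    bands <- c("L3", "L2", "L5")
    adjacency <- tibble(
      a = c("L1", "L1", "L7", "L6", "L7", "L4", "L4", "L4", "L3", "L2"),
      b = c("L6", "L7", "L6", "L4", "L4", "L3", "L2", "L5", "L2", "L5")
    )
    names <- paste0("L", 1:7)
  } else {
    nest <- list(cx = 1500, cy = 1050, radii = c(450, 900, 1150),
                 labels = c("E5", "E9", "E4"),
                 sector = list(ring = 2L, from = 0, to = 2.7, label = "E8"))
    discs <- list(
      list(cx = 2500, cy = 2550, r = 360, label = "E1"),
      list(cx = 600, cy = 2600, r = 330, label = "E7")
    )
    bands <- c("E3", "E6", "E2")
    adjacency <- tibble(
      a = c("E5", "E5", "E9", "E9", "E8", "E4", "E4", "E4", "E3", "E6",
            "E1", "E7"),
      b = c("E9", "E8", "E8", "E4", "E4", "E3", "E6", "E2", "E6", "E2",
            "E2", "E3")
    )
    names <- paste0("E", 1:9)
  }
  region_at <- function(x, y) {
    lab <- band_of(x, y, bands)
    for (d in discs) {
      hit <- (x - d$cx)^2 + (y - d$cy)^2 <= d$r^2
      lab[hit] <- d$label
    }
    r <- sqrt((x - nest$cx)^2 + (y - nest$cy)^2)
    ring <- rep(0L, length(x))
    for (i in rev(seq_along(nest$radii))) ring[r <= nest$radii[i]] <- i
    for (i in seq_along(nest$radii)) lab[ring == i] <- nest$labels[i]
    sec <- nest$sector
    if (!is.null(sec)) {
      ang <- atan2(y - nest$cy, x - nest$cx) %% (2 * pi)
      hit <- ring == sec$ring & ang >= sec$from & ang < sec$to
      lab[hit] <- sec$label
    }
    lab
  }
  new_layout(field, region_at, names, adjacency, vessel_plan, stage = stage)
}

sample_vessels <- function(layout, archetypes) {
  plan <- layout$vessel_plan
  if (is.null(plan) || plan$n == 0L) {
    return(vessel_geometry(list(), source = "synthetic")[0, ])
  }
  w <- setNames(rep(plan$default_weight, nrow(archetypes)), archetypes$name)
  for (role in names(plan$role_weights)) {
    w[archetypes$name[archetypes$role == role]] <- plan$role_weights[[role]]
  }
  polys <- vector("list", plan$n)
  centers <- matrix(NA_real_, plan$n, 2)
  made <- 0L
  guard <- 0L
  while (made < plan$n && guard < plan$n * 200L) {
    guard <- guard + 1L
    cx <- runif(1, 0, layout$field[1])
    cy <- runif(1, 0, layout$field[2])
    reg <- layout$region_at(cx, cy)
    if (runif(1) > w[[reg]]) next
    made <- made + 1L
    len <- runif(1, plan$length_range[1], plan$length_range[2])
    wid <- runif(1, plan$width_range[1], plan$width_range[2])
    ang <- runif(1, 0, pi)
    polys[[made]] <- rect_ribbon(cx, cy, len, wid, ang)
    centers[made, ] <- c(cx, cy)
  }
  vs <- vessel_geometry(polys[seq_len(made)], source = "synthetic")
  vs$cx <- centers[seq_len(made), 1]
  vs$cy <- centers[seq_len(made), 2]
  vs
}

# uniform points inside a ribbon polygon (rotated rectangle)
points_in_ribbon <- function(poly, n) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  p0 <- poly[1, ]; u <- poly[2, ] - poly[1, ]; v <- poly[4, ] - poly[1, ]
  s <- runif(n); t <- runif(n)
  cbind(p0[1] + s * u[1] + t * v[1], p0[2] + s * u[2] + t * v[2])
}

draw_intensities <- function(phenotypes, intensity_model) {
  markers <- unique(intensity_model$marker)
  n <- length(phenotypes)
  out <- matrix(NA_real_, n, length(markers), dimnames = list(NULL, markers))
  for (mk in markers) {
    sub <- intensity_model[intensity_model$marker == mk, ]
    ml <- setNames(sub$meanlog, sub$phenotype)[phenotypes]
    sl <- setNames(sub$sdlog, sub$phenotype)[phenotypes]
    out[, mk] <- rlnorm(n, ml, sl)
  }
  as_tibble(out)
}

#' Generate a synthetic tissue sample
#'
#' Places cells by an inhomogeneous Poisson process (thinning of a
#' homogeneous envelope): within each region the expected number of cells of
#' a phenotype is `density x composition fraction x region area`. Each cell
#' then receives marker intensities from its phenotype's entry in the
#' intensity model. Vessel ribbons are sampled per the layout's vessel plan,
#' endothelial cells are scattered along them, and vascular CAFs are
#' repositioned next to a nearby vessel wall with a distance-decay offset
#' (perivascular enrichment).
#'
#' @param layout A `caf_layout` (see [niche_layout()], [layout_single()]).
#' @param archetypes Archetype table covering every region name in the layout.
#' @param intensity_model See [default_intensity_model()].
#' @param seed Integer seed; identical seeds give identical output.
#' @param sample_id,stage Metadata stamped on every cell.
#' @param density_factor Multiplier on all archetype densities.
#' @return A list with `cells` (tibble: `cell_id`, `sample_id`, `stage`,
#'   `x_um`, `y_um`, marker intensity columns, `true_phenotype`,
#'   `true_region`), `vessels` (vessel geometry tibble) and `truth`
#'   (`caf_ground_truth`: `region_at`, `k_true`, `adjacency`, `archetypes`).
#' @export
generate_tissue <- function(layout, archetypes, intensity_model = default_intensity_model(),
                            seed = 1L, sample_id = "S1", stage = layout$stage,
                            density_factor = 1) {
  if (!inherits(layout, "caf_layout")) abort("`layout` must be a `caf_layout`.")
  validate_archetypes(archetypes)
  if (any(layout$field <= 0)) abort("Layout field must have positive extent.")
  if (density_factor <= 0) abort("`density_factor` must be > 0.")
  used <- archetypes[archetypes$name %in% layout$region_names, ]
  if (!all(layout$region_names %in% used$name)) {
    abort("Archetype table does not cover every region in the layout.")
  }
  withr::with_seed(seed, {
    dens_um2 <- setNames(used$density * density_factor / 1e6, used$name)
    dmax <- max(dens_um2)
    area <- prod(layout$field)
    n0 <- rpois(1, dmax * area)
    x <- runif(n0, 0, layout$field[1])
    y <- runif(n0, 0, layout$field[2])
    reg <- layout$region_at(x, y)
    keep <- runif(n0) < dens_um2[reg] / dmax
    x <- x[keep]; y <- y[keep]; reg <- reg[keep]

    # phenotype by region composition
    ph_names <- caf_phenotypes()
    comp <- as.matrix(used[ph_names])
    rownames(comp) <- used$name
    ph <- character(length(x))
    for (rn in unique(reg)) {
      idx <- which(reg == rn)
      ph[idx] <- sample(ph_names, length(idx), replace = TRUE, prob = comp[rn, ])
    }

    vessels <- sample_vessels(layout, used)
    plan <- layout$vessel_plan
    if (nrow(vessels) > 0 && !is.null(plan)) {
      # endothelial cells lining the vessel lumen
      for (i in seq_len(nrow(vessels))) {
        poly <- vessels$polygon[[i]]
        nv <- rpois(1, polygon_area(poly) * plan$endothelial_per_um2)
        if (nv > 0) {
          pts <- points_in_ribbon(poly, nv)
          x <- c(x, pts[, 1]); y <- c(y, pts[, 2])
          reg <- c(reg, layout$region_at(pts[, 1], pts[, 2]))
          ph <- c(ph, rep("endothelial", nv))
        }
      }
      # perivascular enrichment: move a fraction of vCAFs next to the
      # nearest vessel wall (distance-decay offset, capped)
      vc <- matrix(c(vessels$cx, vessels$cy), ncol = 2)
      for (sub in names(plan$perivascular)) {
        par <- plan$perivascular[[sub]]
        cand <- which(ph == sub & runif(length(ph)) < par$prob)
        if (!length(cand)) next
        d2 <- cross_dist2(cbind(x[cand], y[cand]), vc)
        nearest <- max.col(-d2)
        ok <- sqrt(d2[cbind(seq_along(cand), nearest)]) <= plan$search_radius
        for (k in which(ok)) {
          i <- cand[k]; vi <- nearest[k]
          poly <- vessels$polygon[[vi]]
          axis <- poly[2, ] - poly[1, ]
          axis <- axis / sqrt(sum(axis^2))
          norm <- c(-axis[2], axis[1])
          halfw <- sqrt(sum((poly[4, ] - poly[1, ])^2)) / 2
          along <- runif(1, -0.5, 0.5) * sqrt(sum((poly[2, ] - poly[1, ])^2))
          off <- (halfw + min(rexp(1, 1 / par$decay), plan$max_offset)) *
            sample(c(-1, 1), 1)
          px <- vc[vi, 1] + along * axis[1] + off * norm[1]
          py <- vc[vi, 2] + along * axis[2] + off * norm[2]
          x[i] <- min(max(px, 0), layout$field[1])
          y[i] <- min(max(py, 0), layout$field[2])
          reg[i] <- layout$region_at(x[i], y[i])
        }
      }
    }

    cells <- bind_cols(
      tibble(
        cell_id = paste0(sample_id, "_", seq_along(x)),
        sample_id = rep(sample_id, length(x)),
        stage = rep(stage %||% NA_character_, length(x)),
        x_um = x, y_um = y
      ),
      draw_intensities(ph, intensity_model)
    )
    cells$true_phenotype <- ph
    cells$true_region <- reg

    truth <- structure(
      list(
        region_at = layout$region_at,
        k_true = length(unique(layout$region_names)),
        adjacency = layout$adjacency,
        archetypes = used,
        field = layout$field,
        stage = stage,
        seed = seed
      ),
      class = "caf_ground_truth"
    )
    list(cells = cells, vessels = vessels, truth = truth)
  })
}

#' Simulate a tumor with the planted niche architecture
#'
#' Convenience wrapper: builds the staged layout ([niche_layout()]) and the
#' default intensity model, then calls [generate_tissue()].
#'
#' @inheritParams generate_tissue
#' @param stage `"early"` (9 planted archetypes) or `"late"` (7).
#' @param ... Passed to [niche_layout()].
#' @return As [generate_tissue()].
#' @export
#' @examples
#' sim <- niche_architecture("late", seed = 1)
#' dplyr::count(sim$cells, true_region)
niche_architecture <- function(stage = c("early", "late"), seed = 1L,
                               density_factor = 1, sample_id = NULL, ...) {
  stage <- match.arg(stage)
  layout <- niche_layout(stage, ...)
  sample_id <- sample_id %||% paste0(toupper(substr(stage, 1, 1)), "_s", seed)
  generate_tissue(layout, builtin_archetypes(stage),
                  seed = seed, sample_id = sample_id, stage = stage,
                  density_factor = density_factor)
}

#' Simulate a cohort of tumors
#'
#' @param stage Stage label for all samples.
#' @param n_samples Number of tumors.
#' @param seed Cohort seed; per-sample seeds are derived deterministically.
#' @param ... Passed to [niche_architecture()].
#' @return A list with `cells` (all samples stacked), `vessels` (stacked,
#'   with a `sample_id` column) and `truths` (list of per-sample ground
#'   truths).
#' @export
simulate_cohort <- function(stage, n_samples, seed = 1L, ...) {
  sims <- lapply(seq_len(n_samples), function(i) {
    sid <- sprintf("%s_%02d", stage, i)
    niche_architecture(stage, seed = child_seed(seed, i), sample_id = sid, ...)
  })
  vessels <- bind_rows(lapply(sims, function(s) {
    if (nrow(s$vessels) == 0) return(NULL)
    mutate(s$vessels, sample_id = s$cells$sample_id[1])
  }))
  list(
    cells = bind_rows(lapply(sims, `[[`, "cells")),
    vessels = vessels,
    truths = lapply(sims, `[[`, "truth")
  )
}
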