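#' Per-neighborhood phenotype composition
#'
#' Counts, for every raster grid point, the classified cells of each
#' phenotype lying within the closed ball of the grid's neighborhood radius
#' (distance <= r). Candidate (cell, grid point) pairs are generated through
#' the lattice structure (each cell can only fall within r of a bounded
#' block of lattice points), so the count agrees exactly with brute-force
#' distance checking while scaling to large fields. Vessel tiles, when
#' supplied, are counted as an additional pseudo-phenotype `"vessel"`.
#' Unclassified cells are never counted.
#'
#' @param cells Phenotyped cell table.
#' @param grid A `caf_grid` from [make_grid()].
#' @param tiles Optional tile table from [tile_vessels()].
#' @param phenotypes Phenotype columns to tally; defaults to the panel's
#'   label set.
#' @return A `caf_composition` tibble: `grid_id`, `ix`, `iy`, `x_um`,
#'   `y_um`, one count column per phenotype, `total`, `empty` flag;
#'   attribute `normalization = "counts"` plus the grid attributes.
#' @export
compute_neighborhoods <- function(cells, grid, tiles = NULL,
                                  phenotypes = caf_phenotypes()) {
  assert_cells(cells, phenotyped = TRUE)
  spacing <- grid_attr(grid, "spacing")
  radius <- grid_attr(grid, "radius")
  origin <- grid_attr(grid, "origin")
  nx <- grid_attr(grid, "nx"); ny <- grid_attr(grid, "ny")

  pts <- filter(cells, .data$phenotype %in% phenotypes)
  pts <- tibble(x = pts$x_um, y = pts$y_um, phenotype = pts$phenotype)
  if (!is.null(tiles) && nrow(tiles) > 0) {
    pts <- bind_rows(pts, tibble(x = tiles$x_um, y = tiles$y_um, phenotype = "vessel"))
    phenotypes <- c(phenotypes, "vessel")
  }

  counts <- matrix(0L, nrow(grid), length(phenotypes),
                   dimnames = list(NULL, phenotypes))
  if (nrow(pts) > 0) {
    # lattice index ranges each point can reach
    ix_lo <- pmax(ceiling((pts$x - radius - origin[1]) / spacing) + 1L, 1L)
    ix_hi <- pmin(floor((pts$x + radius - origin[1]) / spacing) + 1L, nx)
    iy_lo <- pmax(ceiling((pts$y - radius - origin[2]) / spacing) + 1L, 1L)
    iy_hi <- pmin(floor((pts$y + radius - origin[2]) / spacing) + 1L, ny)
    reach <- pmax(ix_hi - ix_lo + 1L, 0L) * pmax(iy_hi - iy_lo + 1L, 0L)
    keep <- reach > 0L
    idx <- rep(which(keep), reach[keep])
    # enumerate candidate lattice points per cell
    off <- sequence(reach[keep]) - 1L
    w <- (ix_hi - ix_lo + 1L)[idx]
    cand_ix <- ix_lo[idx] + off %% w
    cand_iy <- iy_lo[idx] + off %/% w
    gx <- origin[1] + (cand_ix - 1L) * spacing
    gy <- origin[2] + (cand_iy - 1L) * spacing
    ok <- (pts$x[idx] - gx)^2 + (pts$y[idx] - gy)^2 <= radius^2 + 1e-9
    gid <- (cand_iy[ok] - 1L) * nx + cand_ix[ok]
    ph <- factor(pts$phenotype[idx][ok], levels = phenotypes)
    tab <- table(gid = gid, ph = ph)
    counts[as.integer(rownames(tab)), ] <- counts[as.integer(rownames(tab)), , drop = FALSE] +
      unclass(tab)
  }

  out <- bind_cols(select(as_tibble(grid), "grid_id", "ix", "iy", "x_um", "y_um"),
                   as_tibble(counts))
  out$total <- as.integer(rowSums(counts))
  out$empty <- out$total == 0L
  structure(out,
            phenotypes = phenotypes, normalization = "counts",
            spacing = spacing, radius = radius, nx = nx, ny = ny, origin = origin,
            class = c("caf_composition", class(out)))
}

#' Normalize a composition matrix
#'
#' @param comp A `caf_composition`.
#' @param mode `"fraction"` (divide each row by its total; empty rows stay
#'   zero and flagged) or `"none"`.
#' @return The composition with updated `normalization` attribute.
#' @export
normalize_composition <- function(comp, mode = c("fraction", "none")) {
  if (!inherits(comp, "caf_composition")) abort("`comp` must come from compute_neighborhoods().")
  if (!is.character(mode)) abort('`mode` must be "fraction" or "none".')
  mode <- match.arg(mode)
  if (mode == "none" || attr(comp, "normalization") == "fraction") return(comp)
  ph <- attr(comp, "phenotypes")
  m <- as.matrix(comp[ph])
  tot <- comp$total
  m[tot > 0, ] <- m[tot > 0, , drop = FALSE] / tot[tot > 0]
  comp[ph] <- as_tibble(m)
  attr(comp, "normalization") <- "fraction"
  comp
}

composition_features <- function(comp) {
  as.matrix(comp[attr(comp, "phenotypes")])
}
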