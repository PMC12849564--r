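#' Read a per-cell measurement table
#'
#' Reads delimited text (comma or tab, detected from the header line) and
#' maps measurement-export column names onto the canonical schema via
#' `column_map`, e.g. `c("Centroid X µm" = "x_um")`. Coordinates are
#' asserted to be micrometres (finite numerics); duplicate cell ids are
#' rejected.
#'
#' @param path File path.
#' @param column_map Named character vector: names are file columns, values
#'   canonical columns.
#' @param markers Marker columns that must parse as positive numerics.
#' @return A validated cell tibble.
#' @export
read_cell_table <- function(path, column_map = NULL, markers = NULL) {
  if (!file.exists(path)) abort(paste0("Cell table not found: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  tb <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (!is.null(column_map)) {
    hit <- intersect(names(column_map), names(tb))
    names(tb)[match(hit, names(tb))] <- column_map[hit]
  }
  if (!all(c("x_um", "y_um") %in% names(tb))) {
    cand <- grep("centroid|^x$|^y$|x_um|y_um", names(tb), ignore.case = TRUE, value = TRUE)
    abort(paste0("Missing coordinate columns x_um/y_um. Candidate columns in file: ",
                 paste(cand, collapse = ", "),
                 ". Provide `column_map` to rename them."))
  }
  if (!"cell_id" %in% names(tb)) tb$cell_id <- as.character(seq_len(nrow(tb)))
  if (anyDuplicated(tb$cell_id)) {
    abort(paste0("Duplicated cell_id values, e.g. ",
                 tb$cell_id[duplicated(tb$cell_id)][1]))
  }
  for (col in c("x_um", "y_um", markers)) {
    v <- tb[[col]]
    if (is.null(v)) abort(paste0("Missing column `", col, "`."))
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        abort(paste0("Non-numeric values in `", col, "` at row(s): ",
                     paste(head(bad, 5), collapse = ", ")))
      }
      tb[[col]] <- vn
    }
  }
  assert_cells(tb, markers = markers)
  as_tibble(tb)
}

#' Write a cell table as CSV
#'
#' @param cells Cell tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  readr::write_csv(cells, path, progress = FALSE)
  invisible(path)
}

#' Read vessel polygons from GeoJSON
#'
#' Accepts a FeatureCollection of `Polygon` features (outer rings only; the
#' closing vertex is dropped if repeated).
#'
#' @param path GeoJSON file.
#' @return A vessel geometry tibble (see [vessel_geometry()]).
#' @export
read_vessels_geojson <- function(path) {
  if (!file.exists(path)) abort(paste0("GeoJSON not found: ", path))
  gj <- jsonlite::read_json(path)
  feats <- gj$features %||% list()
  polys <- lapply(seq_along(feats), function(i) {
    geom <- feats[[i]]$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon")) {
      abort(paste0("Feature ", i, " is not a Polygon."))
    }
    ring <- geom$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (nrow(m) > 3 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  })
  if (!length(polys)) return(vessel_geometry(list())[0, ])
  vessel_geometry(polys, source = "annotation")
}

#' Write vessel polygons to GeoJSON
#'
#' @param vessels Vessel geometry tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vessels_geojson <- function(vessels, path) {
  feats <- lapply(seq_len(nrow(vessels)), function(i) {
    poly <- vessels$polygon[[i]]
    ring <- lapply(seq_len(nrow(poly)), function(j) c(poly[j, 1], poly[j, 2]))
    ring[[length(ring) + 1L]] <- ring[[1]]
    list(
      type = "Feature",
      properties = list(vessel_id = vessels$vessel_id[i],
                        source = vessels$source[i]),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize / restore a fitted region model
#'
#' The SOM codebook, scaling parameters, Davies-Bouldin curve and
#' neighborhood labels go into one JSON container (the ground-truth closure
#' of synthetic data is not serialized).
#'
#' @param model A `caf_region_model`.
#' @param path JSON path.
#' @return `path` / a `caf_region_model`.
#' @export
write_region_model <- function(model, path) {
  payload <- list(
    k = model$k,
    db_curve = model$db_curve,
    codebook = model$som$codebook,
    center = model$som$center,
    scale = model$som$scale,
    grid_shape = model$som$grid_shape,
    node_region = model$node_region,
    labels = model$labels,
    comp_meta = model$comp_meta,
    phenotypes = model$phenotypes,
    normalization = model$normalization,
    grid_dims = model$grid_dims,
    seed = model$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_region_model
#' @param path JSON path written by [write_region_model()].
#' @export
read_region_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  som <- structure(
    list(codebook = as.matrix(p$codebook), center = unlist(p$center),
         scale = unlist(p$scale), grid_shape = p$grid_shape, seed = p$seed),
    class = "caf_som"
  )
  colnames(som$codebook) <- p$phenotypes
  structure(
    list(som = som, db_curve = as_tibble(p$db_curve), k = p$k,
         labels = p$labels, node_region = p$node_region,
         comp_meta = as_tibble(p$comp_meta), phenotypes = p$phenotypes,
         normalization = p$normalization,
         grid_dims = setNames(unlist(p$grid_dims), c("nx", "ny")),
         seed = p$seed),
    class = "caf_region_model"
  )
}

#' Default pipeline configuration
#'
#' All stage parameters with their published or conventional defaults:
#' 50 µm neighborhood radius, spacing equal to the radius, 10 µm tile side,
#' 10% border cutoff, 10 µm (means) and 100 µm (distributions) censor
#' radii.
#'
#' @param ... Overrides.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    radius = 50, spacing = 50, tile_side = 10,
    som_shape = c(10, 10), som_iterations = 60, k_range = 2:15,
    cutoff = 10, censor_radius = 10, censor_radius_far = 100,
    calibration = "gmm", seed = 1L
  )
  modifyList(cfg, list(...))
}

#' Run the full analysis pipeline
#'
#' Executes phenotyping, vessel tiling, neighborhoods, region clustering,
#' border interactions, pseudo-space and distance analysis on one cell
#' table, writing every intermediate artifact plus the fully resolved
#' configuration to `out_dir`. Re-running with the same inputs and config
#' reproduces identical outputs.
#'
#' @param cells Cell table (raw intensities).
#' @param vessels Optional vessel geometry tibble.
#' @param config See [pipeline_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @return A list of all stage results, invisibly when writing.
#' @export
run_pipeline <- function(cells, vessels = NULL, config = pipeline_config(),
                         out_dir = NULL) {
  calls <- calibrate_thresholds(cells, method = config$calibration)
  cells <- classify_cells(cells, calls)
  tiles <- if (!is.null(vessels) && nrow(vessels) > 0) {
    tile_vessels(vessels, tile_side = config$tile_side)
  } else NULL
  grid <- make_grid(cells, spacing = config$spacing, radius = config$radius)
  comp <- compute_neighborhoods(cells, grid)
  model <- cluster_regions(comp, k_range = config$k_range,
                           som_shape = config$som_shape,
                           iterations = config$som_iterations,
                           seed = config$seed)
  raster <- region_map(model, grid)
  inter <- interaction_matrix(boundary_edges(raster))
  graph <- threshold_graph(inter, cutoff = config$cutoff)
  ps <- pseudospace(comp)
  dists <- if (!is.null(tiles)) {
    nearest_distances(cells, targets = "vessel", tiles = tiles,
                      censor_radius = config$censor_radius_far)
  } else NULL
  res <- list(calls = calls, cells = cells, tiles = tiles, grid = grid,
              comp = comp, model = model, raster = raster,
              interactions = inter, graph = graph, pseudospace = ps,
              distances = dists, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(calls, file.path(out_dir, "thresholds.csv"), progress = FALSE)
    write_cell_table(cells, file.path(out_dir, "cells_phenotyped.csv"))
    if (!is.null(tiles)) readr::write_csv(tiles, file.path(out_dir, "vessel_tiles.csv"),
                                          progress = FALSE)
    readr::write_csv(as_tibble(comp), file.path(out_dir, "neighborhoods.csv"),
                     progress = FALSE)
    write_region_model(model, file.path(out_dir, "region_model.json"))
    readr::write_csv(tidy(model), file.path(out_dir, "region_labels.csv"),
                     progress = FALSE)
    readr::write_csv(graph, file.path(out_dir, "interaction_edges.csv"),
                     progress = FALSE)
    readr::write_csv(as_tibble(ps), file.path(out_dir, "pseudospace.csv"),
                     progress = FALSE)
    if (!is.null(dists)) {
      readr::write_csv(summarise_distances(dists),
                       file.path(out_dir, "distance_summary.csv"), progress = FALSE)
    }
    cfg <- config
    cfg$package_version <- as.character(utils::packageVersion("cafniche"))
    jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}
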