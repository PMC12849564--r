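#' Plot the Davies-Bouldin model-selection curve
#'
#' @param object A `caf_region_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.caf_region_model <- function(object, ...) {
  ggplot2::ggplot(object$db_curve, ggplot2::aes(x = .data$k, y = .data$db)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::labs(x = "candidate number of regions k",
                  y = "Davies-Bouldin index",
                  title = paste0("Selected k = ", object$k)) +
    ggplot2::theme_minimal()
}

#' Positional map of region labels
#'
#' Region color-coded plot of the raster neighborhoods (image convention:
#' y axis reversed).
#'
#' @param model A `caf_region_model`.
#' @return A ggplot.
#' @export
plot_region_map <- function(model) {
  df <- tidy(model) |> filter(!is.na(.data$region))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                   fill = factor(.data$region))) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = "region") +
    ggplot2::theme_minimal()
}

#' Pseudo-space abundance curves
#'
#' @param object A `caf_pseudospace`.
#' @param phenotypes Phenotypes to draw (default: the CAF substates plus
#'   immune and tumor).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.caf_pseudospace <- function(object,
                                     phenotypes = c("immune", "tumor", "mCAF1",
                                                    "mCAF2", "vCAF1", "vCAF2"),
                                     ...) {
  ph <- intersect(phenotypes, attr(object, "phenotypes"))
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("position", paste0(ph, "_smooth"))],
    -"position", names_to = "phenotype", values_to = "abundance"
  ) |>
    mutate(phenotype = sub("_smooth$", "", .data$phenotype))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$abundance,
                                     color = .data$phenotype)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pseudo-space (neighborhood rank)",
                  y = "smoothed composition fraction") +
    ggplot2::theme_minimal()
}

#' Region-interaction network plot
#'
#' Draws retained edges of the thresholded shared-border graph on a circular
#' layout (a minimal stand-in for chord/network diagrams).
#'
#' @param object A `caf_interactions`.
#' @param cutoff Border percentage cutoff.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.caf_interactions <- function(object, cutoff = 10, ...) {
  labs <- rownames(object$P)
  theta <- seq(0, 2 * pi, length.out = length(labs) + 1L)[seq_along(labs)]
  nodes <- tibble(region = labs, x = cos(theta), y = sin(theta))
  edges <- threshold_graph(object, cutoff) |> filter(.data$retained)
  edges <- edges |>
    left_join(nodes, by = c(region_a = "region")) |>
    rename(xa = "x", ya = "y") |>
    left_join(nodes, by = c(region_b = "region")) |>
    rename(xb = "x", yb = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb,
                                       linewidth = pmax(.data$pct_ab, .data$pct_ba)),
                          color = "grey50") +
    ggplot2::geom_point(data = nodes, ggplot2::aes(x = .data$x, y = .data$y), size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = 1.15 * .data$x, y = 1.15 * .data$y,
                                    label = .data$region)) +
    ggplot2::scale_linewidth(range = c(0.3, 2), name = "% shared border") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
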