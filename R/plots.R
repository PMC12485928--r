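#' Map of cells and their nearest-anchor linkages
#'
#' Scatter of cell centroids (anchors emphasized) with a segment from each
#' non-anchor cell to its nearest anchor.  For 3D tables the x-y projection
#' is drawn.
#'
#' @param cells Cells tibble with `is_anchor`.
#' @param edges Edge tibble from [nearest_anchor_edges()].
#' @param point_size Point size (default 0.5).
#' @return A ggplot object.
#' @export
plot_edge_map <- function(cells, edges, point_size = 0.5) {
  seg <- edges |>
    dplyr::inner_join(dplyr::select(cells, "cell_id", "x", "y"),
                      by = c(source_id = "cell_id")) |>
    dplyr::inner_join(dplyr::select(cells, "cell_id", xend = "x", yend = "y"),
                      by = c(anchor_id = "cell_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      linewidth = 0.2, color = "grey60") +
    ggplot2::geom_point(data = cells,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$is_anchor),
      size = point_size) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                                labels = c("other", "anchor"), name = NULL) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Distance-distribution boxplots per cell type
#'
#' Tukey boxplots of nearest-anchor distances per cell type, optionally
#' faceted by a grouping column.
#'
#' @param edges Edge tibble.
#' @param cells Cells tibble.
#' @param level Typology level for the cell-type axis (default `"l3"`).
#' @param group_key Optional metadata column to facet by.
#' @return A ggplot object.
#' @export
plot_distance_distributions <- function(edges, cells, level = "l3",
                                        group_key = NULL) {
  col <- level_column(level)
  dat <- edges |>
    dplyr::inner_join(
      dplyr::select(cells, dplyr::all_of(c("cell_id", col, group_key))),
      by = c(source_id = "cell_id"))
  p <- ggplot2::ggplot(dat,
    ggplot2::aes(x = stats::reorder(.data[[col]], .data$distance,
                                    FUN = stats::median),
                 y = .data$distance)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "distance to nearest anchor (µm)") +
    ggplot2::theme_minimal()
  if (!is.null(group_key)) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(paste("~", group_key)))
  }
  p
}

#' Neighborhood composition heatmap
#'
#' Tile plot of the mean composition vector of each final neighborhood.
#'
#' @param model A `cellanchor_nbhd` model.
#' @param comp The composition tibble the model was fitted on.
#' @return A ggplot object.
#' @export
plot_neighborhood_composition <- function(model, comp) {
  dat <- dplyr::inner_join(comp, neighborhood_labels(model), by = "cell_id") |>
    tidyr::pivot_longer(cols = -c("cell_id", "neighborhood"),
                        names_to = "cell_type", values_to = "fraction") |>
    dplyr::group_by(.data$neighborhood, .data$cell_type) |>
    dplyr::summarise(fraction = mean(.data$fraction), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cell_type,
                                    y = .data$neighborhood,
                                    fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean fraction") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_neighborhood_composition
#' @param object A `cellanchor_nbhd` model (for `autoplot`).
#' @param ... Passed on (`comp` is required).
#' @export
autoplot.cellanchor_nbhd <- function(object, ...) {
  plot_neighborhood_composition(object, ...)
}

#' Radial composition profile plot
#'
#' Line plot of cell-type fraction against window size per neighborhood,
#' showing how neighborhood composition depends on spatial scale.
#'
#' @param radial Output of [radial_composition()].
#' @return A ggplot object.
#' @export
plot_radial_composition <- function(radial) {
  ggplot2::ggplot(radial, ggplot2::aes(x = .data$window, y = .data$fraction,
                                       color = .data$cell_type)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10(breaks = unique(radial$window)) +
    ggplot2::facet_wrap(~neighborhood) +
    ggplot2::labs(x = "window size (cells)", y = "mean fraction",
                  color = NULL) +
    ggplot2::theme_minimal()
}
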