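#' Coefficient of variation, in percent
#'
#' The ratio of the standard deviation to the mean of a distance distribution,
#' reported in percent: `100 * sd(x) / mean(x)`.  A CV of 0 means no
#' variation; larger values mean greater relative variability regardless of
#' absolute distances.  Uses the sample (n-1) standard deviation and is
#' invariant under positive rescaling of the values.
#'
#' @param values Numeric vector (distances in um), length >= 2, positive mean.
#' @return The CV in percent.
#' @export
#' @examples
#' coefficient_of_variation(c(1, 2, 3))  # 50
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("insufficient data: coefficient of variation needs n >= 2",
         call. = FALSE)
  }
  m <- mean(values)
  if (!is.finite(m) || m <= 0) {
    stop("domain error: coefficient of variation needs mean > 0", call. = FALSE)
  }
  100 * stats::sd(values) / m
}

#' Summarize nearest-anchor distance distributions per cell type and group
#'
#' Joins the edge table back to the cells table and summarizes the distance
#' distribution per (group, cell type): count, mean, SD, median, quartiles,
#' IQR, and CV (percent).  Quartiles use linear interpolation on the sorted
#' values (`stats::quantile` type 7).  Cells without an edge (nearest anchor
#' beyond the threshold) are simply absent from `edges` and therefore
#' excluded; groups with zero edges are omitted.
#'
#' @param edges An edge tibble from [nearest_anchor_edges()].
#' @param cells The cells tibble the edges were computed from.
#' @param level Typology level whose label defines `cell_type`
#'   (`"l3"` default).
#' @param group_keys Character vector of metadata column names to group by
#'   (e.g. `"region"`, `c("dataset_id", "condition")`); may be empty.
#' @return A tibble with one row per group x cell type: the group keys,
#'   `cell_type`, `n`, `mean`, `sd`, `median`, `q1`, `q3`, `iqr`, `cv`.
#'   `sd` and `cv` are `NA` when `n == 1`.
#' @export
summarize_distances <- function(edges, cells, level = "l3",
                                group_keys = character(0)) {
  col <- level_column(level)
  if (!col %in% names(cells)) {
    stop("state error: cells carry no '", col, "' column", call. = FALSE)
  }
  bad <- setdiff(group_keys, names(cells))
  if (length(bad) > 0L) {
    stop("schema error: unknown group key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(edges) > 0L && !all(edges$source_id %in% cells$cell_id)) {
    stop("consistency error: edge source_id values missing from cells table",
         call. = FALSE)
  }

  joined <- dplyr::inner_join(
    edges,
    dplyr::select(cells, dplyr::all_of(c("cell_id", col, group_keys))),
    by = c(source_id = "cell_id")
  )
  joined$cell_type <- joined[[col]]

  joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_keys, "cell_type")))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$distance),
      sd = stats::sd(.data$distance),
      median = stats::median(.data$distance),
      q1 = unname(stats::quantile(.data$distance, 0.25, type = 7)),
      q3 = unname(stats::quantile(.data$distance, 0.75, type = 7)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      iqr = .data$q3 - .data$q1,
      cv = dplyr::if_else(.data$mean > 0, 100 * .data$sd / .data$mean,
                          NA_real_)
    )
}
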