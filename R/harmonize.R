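#' The eight top-level (L1) cell-type categories
#'
#' The most general level of the three-level typology groups every cell type
#' into eight categories.  Shipping the vocabulary as a packaged constant lets
#' harmonized tables be validated without any external file.
#'
#' @return Character vector of the 8 L1 category names (lower-case).
#' @export
l1_categories <- function() {
  c("endothelial", "epithelial", "hematopoietic precursor", "immune",
    "mesenchymal", "neural", "mixed immune/epithelial", "unknown")
}

#' Normalize a cell-type label
#'
#' Lower-cases, strips surrounding whitespace, and collapses internal runs of
#' whitespace to single spaces.  Idempotent.  Empty or missing labels map to
#' `"unknown"`.
#'
#' @param raw Character vector of raw labels.
#' @return Character vector of normalized labels.
#' @export
#' @examples
#' normalize_label("CD8+ T Cell ")        # "cd8+ t cell"
#' normalize_label("Endothelial   Cell")  # "endothelial cell"
normalize_label <- function(raw) {
  out <- stringr::str_squish(tolower(as.character(raw)))
  out[is.na(out) | out == ""] <- "unknown"
  out
}

#' Attach the three-level typology and ontology annotation to cells
#'
#' Looks up each cell's normalized original label in the crosswalk and fills
#' `label_l3`, `label_l2`, `label_l1`, `cl_label`, `cl_id` and `match_level`.
#' Matching is on normalized labels, so crosswalk files may be written in any
#' casing.  Deterministic and idempotent: re-applying the same crosswalk
#' changes nothing.
#'
#' @param cells A cells tibble with a `label` column.
#' @param crosswalk A crosswalk tibble from [read_crosswalk()].
#' @param on_missing Policy for labels absent from the crosswalk:
#'   `"unknown"` (default; all three levels become `"unknown"`, with a
#'   warning), `"error"` (stop, listing the unmapped labels), or
#'   `"passthrough"` (the normalized original label is used at all three
#'   levels).
#' @return The cells tibble with harmonized-label and ontology columns filled.
#' @export
apply_crosswalk <- function(cells, crosswalk,
                            on_missing = c("unknown", "error", "passthrough")) {
  on_missing <- match.arg(on_missing)
  stopifnot("label" %in% names(cells))
  norm <- normalize_label(cells$label)
  idx <- match(norm, crosswalk$label)

  unmapped <- sort(unique(norm[is.na(idx)]))
  if (length(unmapped) > 0L) {
    if (on_missing == "error") {
      stop("mapping error: labels missing from crosswalk: ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    }
    if (on_missing == "unknown") {
      warning("crosswalk has no entry for ", length(unmapped),
              " label(s); mapped to 'unknown': ",
              paste(utils::head(unmapped, 10L), collapse = ", "),
              call. = FALSE)
    }
  }

  fill <- function(column, fallback) {
    v <- crosswalk[[column]][idx]
    v[is.na(idx)] <- fallback[is.na(idx)]
    v
  }
  miss_default <- if (on_missing == "passthrough") norm else
    rep("unknown", length(norm))
  cells$label_l3 <- fill("label_l3", miss_default)
  cells$label_l2 <- fill("label_l2", miss_default)
  cells$label_l1 <- fill("label_l1", miss_default)
  cells$cl_label <- fill("cl_label", rep(NA_character_, length(norm)))
  cells$cl_id <- fill("cl_id", rep(NA_character_, length(norm)))
  cells$match_level <- fill("match_level", rep(NA_character_, length(norm)))
  cells
}

#' Count distinct labels at each typology level of a crosswalk
#'
#' @param crosswalk A crosswalk tibble.
#' @return A tibble with columns `level` (`original`, `l3`, `l2`, `l1`) and
#'   `n_labels` (number of distinct labels at that level).
#' @export
typology_summary <- function(crosswalk) {
  tibble::tibble(
    level = c("original", "l3", "l2", "l1"),
    n_labels = c(
      dplyr::n_distinct(crosswalk$label),
      dplyr::n_distinct(crosswalk$label_l3),
      dplyr::n_distinct(crosswalk$label_l2),
      dplyr::n_distinct(crosswalk$label_l1)
    )
  )
}

# Resolve a typology level name to the cells-table column holding it.
level_column <- function(level) {
  level <- match.arg(level, c("original", "l1", "l2", "l3"))
  switch(level, original = "label", l1 = "label_l1", l2 = "label_l2",
         l3 = "label_l3")
}
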