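#' Read a nodes.csv table of cell centroids and labels
#'
#' Reads a per-dataset CSV of cell centroids ("nodes"): one row per cell with
#' x, y (and optionally z) coordinates and a cell-type label.  Header matching
#' is case-insensitive; the label column may be called `name`, `cell_type`, or
#' `label`.  Coordinates are multiplied by `pixel_size` so that everything
#' downstream works in micrometers; no raw-pixel state is kept.  Extra columns
#' are carried through untouched as metadata so real per-study files load
#' unmodified.
#'
#' @param path Path to a CSV file with a header row and columns for x, y,
#'   the cell label, and optionally z.
#' @param pixel_size Micrometers per pixel; every coordinate is multiplied by
#'   this factor (default 1, i.e. coordinates already in um).
#' @param id_policy How to assign `cell_id` when the file has no `cell_id`/`id`
#'   column: `"row_index"` (default) uses the 0-based row index, preserving
#'   file order.
#' @return A tibble with columns `cell_id`, `x`, `y` (and `z` for 3D input),
#'   `label`, plus any extra columns from the file.  Blank or missing labels
#'   become `"unknown"`.
#' @export
read_nodes <- function(path, pixel_size = 1, id_policy = c("row_index", "column")) {
  id_policy <- match.arg(id_policy)
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0)
  if (!file.exists(path)) {
    stop("nodes file does not exist: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  lowered <- tolower(names(raw))
  find_col <- function(candidates) {
    hit <- which(lowered %in% candidates)
    if (length(hit) == 0L) NA_integer_ else hit[[1L]]
  }
  ix <- find_col("x")
  iy <- find_col("y")
  iz <- find_col("z")
  ilab <- find_col(c("name", "cell_type", "label", "cell type"))
  iid <- find_col(c("cell_id", "id"))
  missing <- c(if (is.na(ix)) "x", if (is.na(iy)) "y",
               if (is.na(ilab)) "name/cell_type/label")
  if (length(missing) > 0L) {
    stop("nodes schema error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  parse_coord <- function(col, name) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & raw[[col]] != "")
    if (length(bad) > 0L) {
      stop("nodes parse error: non-numeric ", name, " at data row ", bad[[1L]],
           " (value '", raw[[col]][bad[[1L]]], "')", call. = FALSE)
    }
    v
  }

  n <- nrow(raw)
  x <- parse_coord(ix, "x")
  y <- parse_coord(iy, "y")
  z <- if (!is.na(iz)) parse_coord(iz, "z") else NULL
  if (!is.null(z) && n > 0L) {
    n_absent <- sum(is.na(z) | raw[[iz]] == "")
    if (n_absent == n) {
      z <- NULL
    } else if (n_absent > 0L) {
      stop("nodes dimensionality error: z present for some rows but not all ",
           "(", n_absent, " of ", n, " rows blank)", call. = FALSE)
    }
  }
  if (n > 0L && (anyNA(x) || anyNA(y) || !all(is.finite(c(x, y))))) {
    stop("nodes parse error: missing or non-finite x/y coordinate", call. = FALSE)
  }
  if (!is.null(z) && n > 0L && !all(is.finite(z))) {
    stop("nodes parse error: non-finite z coordinate", call. = FALSE)
  }

  label <- if (n > 0L) raw[[ilab]] else character(0)
  label[is.na(label) | trimws(label) == ""] <- "unknown"

  cell_id <- if (!is.na(iid) && id_policy == "column") {
    suppressWarnings(as.integer(raw[[iid]]))
  } else {
    seq_len(n) - 1L
  }
  if (anyDuplicated(cell_id)) {
    stop("nodes schema error: cell_id values are not unique", call. = FALSE)
  }

  out <- tibble::tibble(cell_id = cell_id, x = x * pixel_size, y = y * pixel_size)
  if (!is.null(z)) out$z <- z * pixel_size
  out$label <- label

  used <- stats::na.omit(c(ix, iy, iz, ilab, iid))
  extra <- setdiff(seq_along(raw), used)
  for (j in extra) out[[names(raw)[j]]] <- raw[[j]]
  out
}

#' Write a cells table back to CSV
#'
#' Inverse of [read_nodes()] for harmonized tables: writes every column as-is
#' (coordinates already in um).
#'
#' @param cells A cells tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cells <- function(cells, path) {
  readr::write_csv(cells, path, progress = FALSE)
  invisible(path)
}

#' Write an edges table (cell-to-nearest-anchor linkages)
#'
#' Writes `source_id,anchor_id,distance` with full double precision so a
#' round-trip read reproduces the table.
#'
#' @param edges An edge tibble as returned by [nearest_anchor_edges()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  stopifnot(all(c("source_id", "anchor_id", "distance") %in% names(edges)))
  if (nrow(edges) > 0L) {
    if (anyDuplicated(edges$source_id)) {
      stop("edge table invalid: duplicate source_id rows", call. = FALSE)
    }
    if (any(edges$distance < 0)) {
      stop("edge table invalid: negative distance", call. = FALSE)
    }
  }
  readr::write_csv(edges[, c("source_id", "anchor_id", "distance")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read an edges table written by [write_edges()]
#'
#' @param path Path to an edges CSV (`source_id,anchor_id,distance`).
#' @return A tibble with integer ids and numeric distances.
#' @export
read_edges <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(source_id = readr::col_integer(),
                            anchor_id = readr::col_integer(),
                            distance = readr::col_double()),
    progress = FALSE)
}

# Fixed 12-color qualitative palette cycled over labels when no explicit
# colors are supplied; chosen for categorical distinguishability.
.cellanchor_palette <- c(
  "#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd", "#8c564b",
  "#e377c2", "#7f7f7f", "#bcbd22", "#17becf", "#aec7e8", "#ffbb78"
)

#' Write a label-to-color map
#'
#' Produces the `color map.csv` companion of a nodes/edges export: one row per
#' label with a hex color.  When `colors` is not supplied, colors are cycled
#' deterministically from a fixed 12-color palette in label order, so the same
#' labels always produce byte-identical files.
#'
#' @param labels Character vector of unique cell-type labels.
#' @param path Output CSV path.
#' @param colors Optional named character vector (label -> hex color).
#' @return The color-map tibble (`label`, `hex_color`), invisibly.
#' @export
write_colormap <- function(labels, path, colors = NULL) {
  if (length(labels) == 0L) {
    stop("color map validation error: labels must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("color map validation error: duplicate labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  hex <- if (is.null(colors)) {
    .cellanchor_palette[(seq_along(labels) - 1L) %% length(.cellanchor_palette) + 1L]
  } else {
    unname(colors[labels])
  }
  if (anyNA(hex)) {
    stop("color map validation error: no color supplied for label(s): ",
         paste(labels[is.na(hex)], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(label = labels, hex_color = hex)
  readr::write_csv(out, path, progress = FALSE)
  invisible(out)
}

#' Read a cell-type crosswalk
#'
#' Reads a crosswalk CSV mapping each original cell-type label to the
#' three-level typology (L3 most specific, L1 most general) plus its Cell
#' Ontology annotation (CL label, CL ID) and a match level.  Header matching
#' is tolerant: column names are compared after lower-casing and stripping
#' non-alphanumerics, so `"Original Label"`, `original_label` and `original`
#' all work.  All labels are normalized with [normalize_label()]; exact
#' duplicate rows are collapsed, conflicting duplicates are an error.
#'
#' @param path Path to the crosswalk CSV.
#' @return A tibble with columns `label` (normalized original label),
#'   `label_l3`, `label_l2`, `label_l1`, `cl_label`, `cl_id`, `match_level`;
#'   one row per distinct original label.
#' @export
read_crosswalk <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  key <- gsub("[^a-z0-9]", "", tolower(names(raw)))
  pick <- function(candidates, what, required = TRUE) {
    hit <- which(key %in% candidates)
    if (length(hit) == 0L) {
      if (required) stop("crosswalk schema error: missing column for ", what,
                         call. = FALSE)
      return(NULL)
    }
    raw[[hit[[1L]]]]
  }
  out <- tibble::tibble(
    label = normalize_label(pick(c("original", "originallabel", "originalcelltype",
                                   "celltype", "label"), "original label")),
    label_l3 = normalize_label(pick(c("l3", "levelthree", "level3", "labell3"), "L3")),
    label_l2 = normalize_label(pick(c("l2", "leveltwo", "level2", "labell2"), "L2")),
    label_l1 = normalize_label(pick(c("l1", "levelone", "level1", "labell1"), "L1")),
    cl_label = pick(c("cllabel", "clname", "ontologylabel"), "CL label"),
    cl_id = pick(c("clid", "ontologyid"), "CL ID"),
    match_level = pick(c("matchlevel", "match"), "match level")
  )
  out <- dplyr::distinct(out)
  if (anyDuplicated(out$label)) {
    dup <- unique(out$label[duplicated(out$label)])
    stop("crosswalk consistency error: conflicting mappings for label(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_ml <- setdiff(unique(out$match_level), c("exactMatch", "narrowMatch"))
  if (length(bad_ml) > 0L) {
    stop("crosswalk validation error: unknown match level(s): ",
         paste(bad_ml, collapse = ", "),
         " (allowed: exactMatch, narrowMatch)", call. = FALSE)
  }
  bad_l1 <- setdiff(unique(out$label_l1), l1_categories())
  if (length(bad_l1) > 0L) {
    stop("crosswalk validation error: L1 label(s) outside the 8-category set: ",
         paste(bad_l1, collapse = ", "), call. = FALSE)
  }
  out
}

#' Write a crosswalk table
#'
#' @param crosswalk A crosswalk tibble as returned by [read_crosswalk()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_crosswalk <- function(crosswalk, path) {
  readr::write_csv(crosswalk, path, progress = FALSE)
  invisible(path)
}
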