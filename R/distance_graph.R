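# Coordinate matrix of a cells table (2 or 3 columns); errors on mixed
# dimensionality (a z column must be complete).
coord_matrix <- function(cells) {
  stopifnot(all(c("x", "y") %in% names(cells)))
  has_z <- "z" %in% names(cells)
  if (has_z && nrow(cells) > 0L) {
    if (anyNA(cells$z)) {
      if (all(is.na(cells$z))) {
        has_z <- FALSE
      } else {
        stop("dimensionality error: z present for some cells but not all",
             call. = FALSE)
      }
    }
  }
  m <- if (has_z) cbind(cells$x, cells$y, cells$z) else cbind(cells$x, cells$y)
  if (nrow(cells) > 0L && !all(is.finite(m))) {
    stop("coordinate error: non-finite coordinates", call. = FALSE)
  }
  m
}

#' Mark anchor cells by label at a typology level
#'
#' Flags the cells whose label at `level` equals `anchor_label` (both sides
#' normalized with [normalize_label()]).  The anchor type — typically an
#' endothelial-cell category — is the cell type every other cell's nearest
#' distance is computed to.
#'
#' @param cells A cells tibble; must carry harmonized labels when
#'   `level != "original"`.
#' @param anchor_label Label string defining the anchor cell type.
#' @param level Typology level the label is matched at: `"original"`, `"l1"`,
#'   `"l2"`, or `"l3"`.
#' @return `cells` with a logical `is_anchor` column added; the anchor label
#'   and level are stored as attributes `anchor_label` / `anchor_level`.
#'   An empty selection (no matching cells) is valid and not an error.
#' @export
select_anchors <- function(cells, anchor_label, level = c("l1", "l2", "l3", "original")) {
  level <- match.arg(level)
  col <- level_column(level)
  if (!col %in% names(cells)) {
    stop("state error: cells carry no '", col, "' column; harmonize first ",
         "or use level = 'original'", call. = FALSE)
  }
  cells$is_anchor <- normalize_label(cells[[col]]) == normalize_label(anchor_label)
  attr(cells, "anchor_label") <- normalize_label(anchor_label)
  attr(cells, "anchor_level") <- level
  cells
}

# Shared validation for edge computations; returns list(coords, anchor_idx,
# source_idx) or NULL (zero anchors, warning raised).
edge_inputs <- function(cells, max_distance) {
  stopifnot(is.numeric(max_distance), length(max_distance) == 1L, max_distance > 0)
  if (!"is_anchor" %in% names(cells)) {
    stop("cells carry no 'is_anchor' column; call select_anchors() first",
         call. = FALSE)
  }
  coords <- coord_matrix(cells)
  anchor_idx <- which(cells$is_anchor)
  if (length(anchor_idx) == 0L) {
    warning("no anchor cells in selection; returning empty edge table",
            call. = FALSE)
    return(NULL)
  }
  list(coords = coords, anchor_idx = anchor_idx,
       source_idx = which(!cells$is_anchor))
}

empty_edges <- function() {
  tibble::tibble(source_id = integer(0), anchor_id = integer(0),
                 distance = double(0))
}

#' Nearest-anchor edges under a maximum distance threshold
#'
#' For every non-anchor cell, finds its nearest anchor cell by exact Euclidean
#' distance (2D or 3D) and emits one edge, retained only when the distance is
#' within `max_distance` (inclusive; default 200 um).  Anchor cells receive no
#' edges.  Ties are broken deterministically in favor of the lowest anchor
#' `cell_id`.  Uses an exact KD-tree (RANN, eps = 0), so results agree with
#' the exhaustive scan of [brute_force_nearest()].
#'
#' @param cells A cells tibble with an `is_anchor` column
#'   (see [select_anchors()]); coordinates in um.
#' @param max_distance Maximum distance threshold in um (default 200);
#'   `Inf` retains every nearest-anchor edge.
#' @return A tibble with columns `source_id`, `anchor_id`, `distance` (um),
#'   at most one row per non-anchor cell, in source row order.
#' @export
nearest_anchor_edges <- function(cells, max_distance = 200) {
  inp <- edge_inputs(cells, max_distance)
  if (is.null(inp)) return(empty_edges())
  if (length(inp$source_idx) == 0L) return(empty_edges())

  acoords <- inp$coords[inp$anchor_idx, , drop = FALSE]
  scoords <- inp$coords[inp$source_idx, , drop = FALSE]
  k <- min(2L, length(inp$anchor_idx))
  nn <- RANN::nn2(data = acoords, query = scoords, k = k, eps = 0)
  d1 <- nn$nn.dists[, 1L]
  best <- nn$nn.idx[, 1L]

  # A KD-tree returns *an* arbitrary nearest anchor under exact ties; enforce
  # the lowest-cell_id rule by rescanning rows whose top two neighbors are
  # (near-)equidistant against all anchors.
  if (k == 2L) {
    tied <- which(nn$nn.dists[, 2L] - d1 <= 1e-9 * (1 + d1))
  } else {
    tied <- integer(0)
  }
  anchor_ids <- cells$cell_id[inp$anchor_idx]
  for (i in tied) {
    dd <- sqrt(colSums((t(acoords) - scoords[i, ])^2))
    dmin <- min(dd)
    cand <- which(dd <= dmin + 1e-12 * (1 + dmin))
    best[i] <- cand[which.min(anchor_ids[cand])]
    d1[i] <- dd[best[i]]
  }

  keep <- d1 <= max_distance
  tibble::tibble(
    source_id = cells$cell_id[inp$source_idx][keep],
    anchor_id = anchor_ids[best[keep]],
    distance = d1[keep]
  )
}

#' Exhaustive-scan nearest-anchor edges (verification oracle)
#'
#' Same contract as [nearest_anchor_edges()] via an all-pairs scan.  Intended
#' for verification on small tables (n up to a few thousand); quadratic in
#' memory/time.
#'
#' @inheritParams nearest_anchor_edges
#' @return A tibble with columns `source_id`, `anchor_id`, `distance`.
#' @export
brute_force_nearest <- function(cells, max_distance = 200) {
  inp <- edge_inputs(cells, max_distance)
  if (is.null(inp)) return(empty_edges())
  if (length(inp$source_idx) == 0L) return(empty_edges())

  acoords <- inp$coords[inp$anchor_idx, , drop = FALSE]
  anchor_ids <- cells$cell_id[inp$anchor_idx]
  ord <- order(anchor_ids)          # scan anchors in cell_id order so the
  acoords <- acoords[ord, , drop = FALSE]  # first minimum is the tie-winner
  anchor_ids <- anchor_ids[ord]

  n_src <- length(inp$source_idx)
  best <- integer(n_src)
  dist <- double(n_src)
  at <- t(acoords)
  for (i in seq_len(n_src)) {
    dd <- sqrt(colSums((at - inp$coords[inp$source_idx[i], ])^2))
    j <- which.min(dd)
    best[i] <- j
    dist[i] <- dd[j]
  }
  keep <- dist <= max_distance
  tibble::tibble(
    source_id = cells$cell_id[inp$source_idx][keep],
    anchor_id = anchor_ids[best[keep]],
    distance = dist[keep]
  )
}
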