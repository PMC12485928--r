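#' Neighbor-composition vectors from k-nearest-neighbor windows
#'
#' For each anchor cell, finds its `k` nearest cells of any type (the anchor
#' cell itself is excluded from its own window; other anchor-type cells do
#' count as neighbors) and records the fraction of each cell-type label at
#' `level` among them.  These per-anchor composition vectors are the "local
#' microenvironments" that neighborhood clustering operates on.
#'
#' @param cells A cells tibble with an `is_anchor` column
#'   (see [select_anchors()]).
#' @param k Window size: number of nearest neighbors (default 50).
#' @param level Typology level whose labels define the composition columns.
#' @return A tibble with `cell_id` (anchor) plus one column per label in the
#'   table's vocabulary at `level`; each row is non-negative and sums to 1.
#'   Attributes: `k`, `level`, and `anchor_fraction` (per-row fraction of
#'   window cells that are anchors, used by the enrichment stage).
#' @export
knn_neighbor_composition <- function(cells, k = 50, level = "l3") {
  col <- level_column(level)
  if (!col %in% names(cells)) {
    stop("state error: cells carry no '", col, "' column", call. = FALSE)
  }
  if (!"is_anchor" %in% names(cells)) {
    stop("cells carry no 'is_anchor' column; call select_anchors() first",
         call. = FALSE)
  }
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  n <- nrow(cells)
  if (k >= n) {
    stop("size error: k (", k, ") must be smaller than the number of cells (",
         n, "); the center cell is excluded from its own window",
         call. = FALSE)
  }
  vocab <- sort(unique(cells[[col]]))
  anchor_rows <- which(cells$is_anchor)
  if (length(anchor_rows) == 0L) {
    warning("no anchor cells; returning empty composition table",
            call. = FALSE)
    out <- tibble::as_tibble(stats::setNames(
      c(list(integer(0)), rep(list(double(0)), length(vocab))),
      c("cell_id", vocab)))
    attr(out, "k") <- as.integer(k)
    attr(out, "level") <- level
    attr(out, "anchor_fraction") <- double(0)
    return(out)
  }

  coords <- coord_matrix(cells)
  nn <- RANN::nn2(data = coords, query = coords[anchor_rows, , drop = FALSE],
                  k = k + 1L, eps = 0)
  # Drop the center from each window.  With coincident points the self index
  # is not guaranteed to come first, so remove it wherever it sits (or, if
  # absent among the k+1 due to >k coincident cells, drop the farthest).
  idx <- nn$nn.idx
  win <- matrix(0L, nrow = length(anchor_rows), ncol = k)
  for (i in seq_along(anchor_rows)) {
    row <- idx[i, ]
    self <- match(anchor_rows[i], row)
    if (is.na(self)) self <- k + 1L
    win[i, ] <- row[-self]
  }

  lab_codes <- match(cells[[col]], vocab)
  counts <- matrix(0, nrow = length(anchor_rows), ncol = length(vocab),
                   dimnames = list(NULL, vocab))
  for (j in seq_len(k)) {
    cj <- lab_codes[win[, j]]
    counts[cbind(seq_along(anchor_rows), cj)] <-
      counts[cbind(seq_along(anchor_rows), cj)] + 1
  }
  frac <- counts / k
  anchor_frac <- matrix(cells$is_anchor[win], nrow = length(anchor_rows)) |>
    rowMeans()

  out <- tibble::as_tibble(frac)
  out <- dplyr::bind_cols(tibble::tibble(cell_id = cells$cell_id[anchor_rows]), out)
  attr(out, "k") <- as.integer(k)
  attr(out, "level") <- level
  attr(out, "anchor_fraction") <- anchor_frac
  out
}

#' Extract the numeric matrix from a composition table
#'
#' @param comp A composition tibble from [knn_neighbor_composition()].
#' @return A numeric matrix (rows = anchors, named by `cell_id`; columns =
#'   labels).
#' @export
composition_matrix <- function(comp) {
  m <- as.matrix(comp[, setdiff(names(comp), "cell_id"), drop = FALSE])
  rownames(m) <- comp$cell_id
  m
}

# k-means++ seeding: first center uniform, then each next center sampled with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_centers <- function(x, n_clusters) {
  n <- nrow(x)
  centers <- integer(n_clusters)
  centers[1L] <- sample.int(n, 1L)
  d2 <- colSums((t(x) - x[centers[1L], ])^2)
  for (j in seq_len(n_clusters - 1L) + 1L) {
    if (sum(d2) <= 0) {
      stop("size error: fewer distinct composition vectors than clusters",
           call. = FALSE)
    }
    centers[j] <- sample.int(n, 1L, prob = d2)
    d2 <- pmin(d2, colSums((t(x) - x[centers[j], ])^2))
  }
  x[centers, , drop = FALSE]
}

#' Cluster composition vectors into initial neighborhoods (k-means)
#'
#' Runs k-means on the raw fraction vectors (no standardization — every
#' feature is already a fraction on the same scale): k-means++ seeding, 10
#' restarts keeping the solution with the lowest total within-cluster sum of
#' squares, Lloyd iterations to a fixed point.  Bitwise-reproducible for a
#' fixed seed.  The default of 20 initial clusters follows the workflow of
#' over-clustering first and merging co-localized, compositionally similar
#' clusters afterwards (see [merge_clusters()] / [suggest_merges()]).
#'
#' @param comp A composition tibble from [knn_neighbor_composition()].
#' @param n_clusters Number of initial clusters (default 20).
#' @param seed Integer RNG seed (required; no wall-clock default).
#' @param n_restarts Number of k-means++ restarts (default 10).
#' @return A `cellanchor_nbhd` model: initial cluster assignments, cluster
#'   centers, and an identity merge map (every cluster its own neighborhood
#'   until merged).
#' @export
cluster_compositions <- function(comp, n_clusters = 20, seed, n_restarts = 10) {
  if (missing(seed)) stop("seed is required for clustering", call. = FALSE)
  x <- composition_matrix(comp)
  if (nrow(x) < n_clusters) {
    stop("size error: ", nrow(x), " composition rows < n_clusters = ",
         n_clusters, call. = FALSE)
  }
  fit <- withr::with_seed(as.integer(seed), {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      centers <- kmeanspp_centers(x, n_clusters)
      km <- suppressWarnings(
        stats::kmeans(x, centers = centers, iter.max = 100L,
                      algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  ids <- sort(unique(fit$cluster))
  structure(list(
    assignments = tibble::tibble(cell_id = comp$cell_id,
                                 cluster = as.integer(fit$cluster)),
    centers = fit$centers,
    n_clusters = as.integer(n_clusters),
    seed = as.integer(seed),
    k = attr(comp, "k"),
    level = attr(comp, "level"),
    tot_withinss = fit$tot.withinss,
    merge_map = stats::setNames(as.character(ids), as.character(ids))
  ), class = "cellanchor_nbhd")
}

#' Merge initial clusters into named neighborhoods
#'
#' Applies a user-supplied merge map (initial cluster id -> final
#' neighborhood name) to a clustered model.  Merging is a judgment-based
#' step — clusters that are spatially co-localized and compositionally
#' similar are combined — so the map is always user-authoritative;
#' [suggest_merges()] only proposes one.
#'
#' @param model A `cellanchor_nbhd` model from [cluster_compositions()].
#' @param merge_map Named character vector (names = initial cluster ids,
#'   values = neighborhood names) or a two-column data frame
#'   (`cluster`, `neighborhood`).  Must cover every initial cluster id.
#' @return The model with `merge_map` set; final labels come from
#'   [neighborhood_labels()] / [tidy()].
#' @export
merge_clusters <- function(model, merge_map) {
  stopifnot(inherits(model, "cellanchor_nbhd"))
  if (is.data.frame(merge_map)) {
    merge_map <- stats::setNames(as.character(merge_map$neighborhood),
                                 as.character(merge_map$cluster))
  }
  ids <- as.character(sort(unique(model$assignments$cluster)))
  missing <- setdiff(ids, names(merge_map))
  if (length(missing) > 0L) {
    stop("mapping error: merge_map missing initial cluster id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  model$merge_map <- merge_map[ids]
  model
}

#' Final neighborhood label per anchor cell
#'
#' @param model A `cellanchor_nbhd` model.
#' @return A tibble `cell_id`, `neighborhood`.
#' @export
neighborhood_labels <- function(model) {
  stopifnot(inherits(model, "cellanchor_nbhd"))
  tibble::tibble(
    cell_id = model$assignments$cell_id,
    neighborhood = unname(model$merge_map[as.character(model$assignments$cluster)])
  )
}

#' @export
print.cellanchor_nbhd <- function(x, ...) {
  nb <- neighborhood_labels(x)
  cat("Anchor-centric neighborhood model\n")
  cat("  anchors:", nrow(x$assignments), " window k:", x$k,
      " level:", x$level, "\n")
  cat("  initial clusters:", x$n_clusters,
      " neighborhoods:", dplyr::n_distinct(nb$neighborhood),
      " seed:", x$seed, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an anchor-neighborhood model
#'
#' @param x A `cellanchor_nbhd` model.
#' @param ... Unused.
#' @return One row per anchor cell: `cell_id`, `cluster`, `neighborhood`.
#' @export
tidy.cellanchor_nbhd <- function(x, ...) {
  dplyr::mutate(x$assignments,
                neighborhood = unname(x$merge_map[as.character(.data$cluster)]))
}

#' One-row model summary
#'
#' @param x A `cellanchor_nbhd` model.
#' @param ... Unused.
#' @return A one-row tibble: anchor count, window size, cluster and
#'   neighborhood counts, total within-cluster sum of squares, seed.
#' @export
glance.cellanchor_nbhd <- function(x, ...) {
  tibble::tibble(
    n_anchors = nrow(x$assignments),
    k = x$k,
    n_clusters = x$n_clusters,
    n_neighborhoods = dplyr::n_distinct(unname(x$merge_map)),
    tot_withinss = x$tot_withinss,
    seed = x$seed
  )
}

#' Propose cluster merges from compositional similarity and co-localization
#'
#' Advisory helper emulating the judgment step of combining initial clusters
#' that are spatially co-localized and compositionally similar.
#' Agglomerative: at each step the pair of (possibly already merged) groups
#' with the highest size-weighted-centroid cosine similarity among
#' co-localized pairs is merged, and the merged group's centroid is
#' recomputed, so dissimilar groups cannot fuse through a chain of
#' intermediates.  Merging stops when no co-localized pair reaches
#' `composition_similarity` — or, when `n_target` is given (mirroring a
#' workflow that merges down to a known neighborhood count), when `n_target`
#' groups remain.  Co-occurrence of two groups is the larger of (fraction of
#' one group's anchors with at least one anchor of the other among their
#' `neighbor_k` nearest anchors) and the converse.  The returned map is only
#' a suggestion; the user-supplied map to [merge_clusters()] stays
#' authoritative.
#'
#' @param model A `cellanchor_nbhd` model.
#' @param comp The composition tibble the model was fitted on.
#' @param cells The cells tibble (for anchor coordinates).
#' @param composition_similarity Cosine-similarity threshold in (0, 1]
#'   (default 0.9).
#' @param colocalization Co-occurrence threshold in (0, 1] (default 0.2).
#' @param neighbor_k Anchor-to-anchor neighbor count used for co-occurrence
#'   (default 10).
#' @param n_target Optional target neighborhood count; merging continues to
#'   this count (preferring co-localized, most-similar pairs) regardless of
#'   the similarity threshold.
#' @return A named character merge map over all initial cluster ids
#'   (identity entries for unmerged clusters), each neighborhood named
#'   `N<lowest member cluster id>`.
#' @export
suggest_merges <- function(model, comp, cells, composition_similarity = 0.9,
                           colocalization = 0.2, neighbor_k = 10,
                           n_target = NULL) {
  stopifnot(inherits(model, "cellanchor_nbhd"),
            composition_similarity > 0, composition_similarity <= 1,
            colocalization > 0, colocalization <= 1)
  ids <- sort(unique(model$assignments$cluster))
  sizes <- as.vector(table(factor(model$assignments$cluster, levels = ids)))
  ctr <- model$centers[as.character(ids), , drop = FALSE]

  anchors <- dplyr::inner_join(model$assignments,
    dplyr::select(cells, dplyr::all_of(c("cell_id", "x", "y",
                                         if ("z" %in% names(cells)) "z"))),
    by = "cell_id")
  acoord <- coord_matrix(anchors)
  kk <- min(neighbor_k + 1L, nrow(acoord))
  nn <- RANN::nn2(acoord, acoord, k = kk, eps = 0)
  nb_cluster <- matrix(anchors$cluster[nn$nn.idx[, -1L, drop = FALSE]],
                       nrow = nrow(acoord))

  groups <- as.list(ids)                     # member cluster ids per group
  g_ctr <- ctr                               # weighted centroid per group
  g_size <- sizes
  cos_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  cooccur <- function(ga, gb) {
    rows_a <- anchors$cluster %in% ga
    rows_b <- anchors$cluster %in% gb
    frac_ab <- mean(rowSums(matrix(nb_cluster[rows_a, ] %in% gb,
                                   nrow = sum(rows_a))) > 0)
    frac_ba <- mean(rowSums(matrix(nb_cluster[rows_b, ] %in% ga,
                                   nrow = sum(rows_b))) > 0)
    max(frac_ab, frac_ba)
  }

  repeat {
    ng <- length(groups)
    if (!is.null(n_target) && ng <= n_target) break
    if (ng < 2L) break
    best <- NULL
    best_sim <- -Inf
    for (a_i in seq_len(ng - 1L)) {
      for (b_i in seq(a_i + 1L, ng)) {
        s <- cos_sim(g_ctr[a_i, ], g_ctr[b_i, ])
        if (is.null(n_target) && s < composition_similarity) next
        if (s <= best_sim) next
        if (cooccur(groups[[a_i]], groups[[b_i]]) < colocalization) next
        best <- c(a_i, b_i)
        best_sim <- s
      }
    }
    if (is.null(best)) {
      if (is.null(n_target)) break
      # No co-localized pair left; fall back to the most similar pair so the
      # requested count is still reached.
      for (a_i in seq_len(ng - 1L)) {
        for (b_i in seq(a_i + 1L, ng)) {
          s <- cos_sim(g_ctr[a_i, ], g_ctr[b_i, ])
          if (s > best_sim) { best <- c(a_i, b_i); best_sim <- s }
        }
      }
    }
    a_i <- best[1L]; b_i <- best[2L]
    w <- g_size[c(a_i, b_i)]
    g_ctr[a_i, ] <- (g_ctr[a_i, ] * w[1L] + g_ctr[b_i, ] * w[2L]) / sum(w)
    g_size[a_i] <- sum(w)
    groups[[a_i]] <- c(groups[[a_i]], groups[[b_i]])
    groups <- groups[-b_i]
    g_ctr <- g_ctr[-b_i, , drop = FALSE]
    g_size <- g_size[-b_i]
  }

  out <- character(length(ids))
  names(out) <- as.character(ids)
  for (grp in groups) {
    out[as.character(grp)] <- paste0("N", min(grp))
  }
  out
}

#' Radial (multi-window) neighborhood composition
#'
#' Recomputes neighbor composition over concentric KNN windows of increasing
#' size and averages per final neighborhood, probing how neighborhood
#' composition depends on spatial scale.  At a window equal to the model's
#' own `k` this reproduces the per-neighborhood means of the clustering
#' matrix exactly.
#'
#' @param cells The cells tibble (with `is_anchor`).
#' @param model A `cellanchor_nbhd` model.
#' @param window_sizes Increasing window sizes
#'   (default `c(5, 10, 30, 50, 100, 300)`).
#' @param level Typology level for composition labels (defaults to the
#'   model's).
#' @return A long tibble: `window`, `neighborhood`, `cell_type`, `fraction`,
#'   `n_anchors`.
#' @export
radial_composition <- function(cells, model,
                               window_sizes = c(5, 10, 30, 50, 100, 300),
                               level = model$level) {
  stopifnot(inherits(model, "cellanchor_nbhd"),
            all(diff(window_sizes) > 0), all(window_sizes >= 1))
  labels <- neighborhood_labels(model)
  purrr::map_dfr(window_sizes, function(w) {
    comp <- knn_neighbor_composition(cells, k = w, level = level)
    dplyr::inner_join(comp, labels, by = "cell_id") |>
      tidyr::pivot_longer(cols = -c("cell_id", "neighborhood"),
                          names_to = "cell_type", values_to = "fraction") |>
      dplyr::group_by(.data$neighborhood, .data$cell_type) |>
      dplyr::summarise(n_anchors = dplyr::n_distinct(.data$cell_id),
                       fraction = mean(.data$fraction), .groups = "drop") |>
      dplyr::mutate(window = w, .before = 1L)
  })
}

#' Anchor-type (EC) enrichment per neighborhood
#'
#' The proportion of anchor-type cells among a neighborhood's window cells:
#' each anchor's window anchor-fraction is averaged over the neighborhood's
#' member anchors.
#'
#' @param comp Composition tibble carrying the `anchor_fraction` attribute.
#' @param model A `cellanchor_nbhd` model fitted on `comp` (or on a
#'   composition table over the same anchors).
#' @return A tibble `neighborhood`, `n_anchors`, `ec_enrichment` (in
#'   \[0, 1\]).
#' @export
ec_enrichment <- function(comp, model) {
  af <- attr(comp, "anchor_fraction")
  stopifnot(!is.null(af), length(af) == nrow(comp))
  tab <- dplyr::inner_join(
    tibble::tibble(cell_id = comp$cell_id, anchor_fraction = af),
    neighborhood_labels(model), by = "cell_id")
  dropped <- setdiff(unique(unname(model$merge_map)), unique(tab$neighborhood))
  if (length(dropped) > 0L) {
    warning("neighborhood(s) with no anchors omitted: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  tab |>
    dplyr::group_by(.data$neighborhood) |>
    dplyr::summarise(n_anchors = dplyr::n(),
                     ec_enrichment = mean(.data$anchor_fraction),
                     .groups = "drop")
}

#' Subregion-normalized anchor-type enrichment (fold change)
#'
#' Normalizes neighborhood anchor-type (EC) enrichment per donor by dividing
#' by the anchor-type fraction of the enclosing tissue subregion (e.g.
#' mucosa, submucosa, muscularis externa): for every donor x neighborhood x
#' subregion, fold change = (mean window anchor-fraction of that
#' neighborhood's anchors in that donor-subregion) / (fraction of all the
#' donor-subregion's cells that are anchor-type).  A fold change above 1
#' means the neighborhood is anchor-denser than its subregion average.
#'
#' @param cells Cells tibble with `is_anchor`, subregion and donor columns.
#' @param comp Composition tibble with the `anchor_fraction` attribute.
#' @param model A `cellanchor_nbhd` model.
#' @param subregion_key,donor_key Column names (defaults `"subregion"`,
#'   `"donor_id"`).
#' @return A tibble: donor, subregion, `neighborhood`, `n_anchors`,
#'   `ec_fraction_neighborhood`, `ec_fraction_subregion`, `fold_change`,
#'   `flagged` (`TRUE` with `fold_change = NA` when the subregion denominator
#'   is zero).
#' @export
normalized_ec_enrichment <- function(cells, comp, model,
                                     subregion_key = "subregion",
                                     donor_key = "donor_id") {
  for (colname in c(subregion_key, donor_key)) {
    if (!colname %in% names(cells)) {
      stop("schema error: cells carry no '", colname, "' column",
           call. = FALSE)
    }
  }
  af <- attr(comp, "anchor_fraction")
  stopifnot(!is.null(af))
  background <- cells |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(donor_key, subregion_key)))) |>
    dplyr::summarise(ec_fraction_subregion = mean(.data$is_anchor),
                     .groups = "drop")
  anchors <- tibble::tibble(cell_id = comp$cell_id, anchor_fraction = af) |>
    dplyr::inner_join(neighborhood_labels(model), by = "cell_id") |>
    dplyr::inner_join(
      dplyr::select(cells, dplyr::all_of(c("cell_id", donor_key, subregion_key))),
      by = "cell_id")
  anchors |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(donor_key, subregion_key, "neighborhood")))) |>
    dplyr::summarise(n_anchors = dplyr::n(),
                     ec_fraction_neighborhood = mean(.data$anchor_fraction),
                     .groups = "drop") |>
    dplyr::inner_join(background, by = c(donor_key, subregion_key)) |>
    dplyr::mutate(
      flagged = .data$ec_fraction_subregion <= 0,
      fold_change = dplyr::if_else(.data$flagged, NA_real_,
        .data$ec_fraction_neighborhood / .data$ec_fraction_subregion)
    )
}

#' Neighborhood percentages per group
#'
#' For each group (image, region, donor, ...), the percentage of anchor cells
#' belonging to each neighborhood.  The denominator is the group's anchor
#' cells — neighborhood labels exist only for anchors.  Percentages per group
#' sum to 100; neighborhoods absent from a group appear with 0.
#'
#' @param model A `cellanchor_nbhd` model.
#' @param cells Cells tibble carrying the grouping column.
#' @param group_key Grouping column name (e.g. `"region"`); may be a vector
#'   of column names.
#' @return A tibble: group key(s), `neighborhood`, `n` (anchors),
#'   `percentage`.
#' @export
neighborhood_percentages <- function(model, cells, group_key) {
  bad <- setdiff(group_key, names(cells))
  if (length(bad) > 0L) {
    stop("schema error: unknown group key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  labels <- neighborhood_labels(model)
  anchors <- dplyr::inner_join(
    labels, dplyr::select(cells, dplyr::all_of(c("cell_id", group_key))),
    by = "cell_id")
  all_groups <- dplyr::distinct(cells[, group_key, drop = FALSE])
  have <- dplyr::distinct(anchors[, group_key, drop = FALSE])
  if (nrow(all_groups) > nrow(have)) {
    warning(nrow(all_groups) - nrow(have),
            " group(s) with zero anchor cells omitted", call. = FALSE)
  }
  anchors |>
    dplyr::count(dplyr::across(dplyr::all_of(c(group_key, "neighborhood")))) |>
    tidyr::complete(tidyr::nesting(!!!rlang::syms(group_key)),
                    neighborhood = unique(unname(model$merge_map)),
                    fill = list(n = 0L)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_key))) |>
    dplyr::mutate(percentage = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
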