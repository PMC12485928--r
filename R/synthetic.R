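#' Configuration for synthetic tissue generation
#'
#' Describes a synthetic tissue: a rectangular (or box) field, vessel-like
#' polyline skeletons carrying anchor (endothelial) cells, non-anchor cell
#' types placed at type-specific radial distance laws from the vessels, and
#' optionally planted zones with distinct cell-type mixtures.  Supported
#' distance laws: `"fixed"` (`param1` = distance), `"uniform"` (annulus
#' between `param1` and `param2`), `"exponential"` (`param1` = scale, um).
#'
#' @param extent Field extent in um: length 2 (2D) or 3 (3D box).
#' @param vessels List of polyline vertex matrices (columns = dimensions).
#'   `NULL` (default) lays three horizontal vessels across the field at 1/4,
#'   1/2 and 3/4 of its height.
#' @param anchor_label Label given to anchor cells
#'   (default `"endothelial cell"`).
#' @param anchor_density Anchors per um of vessel arc length (default 0.05,
#'   i.e. one anchor every 20 um along a vessel).
#' @param cell_types Tibble with columns `label`, `n`, `law`, `param1`,
#'   `param2`.  `NULL` gives a default four-type tissue (T cells and
#'   macrophages exponentially concentrated near vessels at scales 20 and
#'   30 um, epithelium spread 10-150 um, fibroblasts at scale 40 um).
#' @param noise_sd Isotropic Gaussian positional jitter, um (default 2).
#' @param zones Optional list of planted zones, each a list with `xmin`,
#'   `xmax`, `ymin`, `ymax` (and `zmin`/`zmax` in 3D), `n` (cell count), and
#'   `mixture` (named probabilities over labels, summing to 1 and including
#'   `anchor_label` with positive mass).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(extent = c(2000, 2000), vessels = NULL,
                             anchor_label = "endothelial cell",
                             anchor_density = 0.05, cell_types = NULL,
                             noise_sd = 2, zones = NULL) {
  stopifnot(length(extent) %in% c(2L, 3L), all(extent > 0),
            anchor_density > 0, noise_sd >= 0)
  dim <- length(extent)
  if (is.null(vessels)) {
    vessels <- lapply(c(0.25, 0.5, 0.75), function(f) {
      v <- cbind(c(0, extent[1L]), c(f, f) * extent[2L])
      if (dim == 3L) v <- cbind(v, extent[3L] / 2)
      v
    })
  }
  for (v in vessels) {
    if (!is.matrix(v) || ncol(v) != dim || nrow(v) < 2L) {
      stop("config error: each vessel must be a polyline matrix with ", dim,
           " columns and >= 2 vertices", call. = FALSE)
    }
  }
  if (is.null(cell_types)) {
    cell_types <- tibble::tibble(
      label = c("t cell", "macrophage", "epithelial cell", "fibroblast"),
      n = c(1500L, 1000L, 1500L, 1000L),
      law = c("exponential", "exponential", "uniform", "exponential"),
      param1 = c(20, 30, 10, 40),
      param2 = c(NA, NA, 150, NA)
    )
  }
  stopifnot(all(c("label", "n", "law", "param1") %in% names(cell_types)))
  if (!"param2" %in% names(cell_types)) cell_types$param2 <- NA_real_
  bad_law <- setdiff(cell_types$law, c("fixed", "uniform", "exponential"))
  if (length(bad_law) > 0L) {
    stop("config error: unknown distance law(s): ",
         paste(bad_law, collapse = ", "), call. = FALSE)
  }
  if (any(cell_types$param1 < 0, na.rm = TRUE)) {
    stop("config error: distance-law parameters must be non-negative",
         call. = FALSE)
  }
  if (!is.null(zones)) {
    for (zn in zones) {
      p <- zn$mixture
      if (abs(sum(p) - 1) > 1e-8) {
        stop("config error: zone mixture must sum to 1", call. = FALSE)
      }
      if (!(anchor_label %in% names(p)) || p[[anchor_label]] <= 0) {
        stop("config error: every zone mixture must include '", anchor_label,
             "' with positive probability", call. = FALSE)
      }
    }
    zones_overlap <- function(a, b) {
      sep <- a$xmax <= b$xmin || b$xmax <= a$xmin ||
             a$ymax <= b$ymin || b$ymax <= a$ymin
      !sep
    }
    if (length(zones) > 1L) {
      for (i in seq_len(length(zones) - 1L)) {
        for (j in seq(i + 1L, length(zones))) {
          if (zones_overlap(zones[[i]], zones[[j]])) {
            stop("config error: zones ", i, " and ", j,
                 " overlap; zones must be disjoint", call. = FALSE)
          }
        }
      }
    }
  }
  structure(list(extent = extent, vessels = vessels,
                 anchor_label = anchor_label, anchor_density = anchor_density,
                 cell_types = cell_types, noise_sd = noise_sd, zones = zones),
            class = "synthetic_config")
}

# Exact point-to-polyline distance: minimum over all segments of all vessels.
dist_to_skeleton <- function(points, vessels) {
  n <- nrow(points)
  if (n == 0L) return(double(0))
  best <- rep(Inf, n)
  for (v in vessels) {
    for (s in seq_len(nrow(v) - 1L)) {
      a <- v[s, ]
      ab <- v[s + 1L, ] - a
      len2 <- sum(ab^2)
      rel <- sweep(points, 2L, a)
      t <- if (len2 > 0) pmin(1, pmax(0, rel %*% ab / len2)) else rep(0, n)
      proj <- outer(as.vector(t), ab)
      best <- pmin(best, sqrt(rowSums((rel - proj)^2)))
    }
  }
  best
}

# Sample points uniformly by arc length on a set of polylines; returns the
# point coordinates and the unit tangent of the generating segment.
sample_on_skeleton <- function(vessels, n) {
  segs <- do.call(rbind, lapply(vessels, function(v) {
    cbind(v[-nrow(v), , drop = FALSE], v[-1L, , drop = FALSE])
  }))
  d <- ncol(segs) / 2L
  a <- segs[, seq_len(d), drop = FALSE]
  b <- segs[, d + seq_len(d), drop = FALSE]
  lens <- sqrt(rowSums((b - a)^2))
  seg <- sample.int(nrow(segs), n, replace = TRUE, prob = lens)
  t <- stats::runif(n)
  pts <- a[seg, , drop = FALSE] +
    (b[seg, , drop = FALSE] - a[seg, , drop = FALSE]) * t
  tangent <- (b[seg, , drop = FALSE] - a[seg, , drop = FALSE]) / lens[seg]
  list(points = pts, tangent = tangent)
}

sample_radial_distance <- function(law, param1, param2, n) {
  switch(law,
    fixed = rep(param1, n),
    uniform = stats::runif(n, param1, param2),
    exponential = stats::rexp(n, rate = 1 / param1))
}

# Unit vectors perpendicular to each tangent: the radial distance law governs
# the distance to the vessel, so displacement must be normal to it (random
# side in 2D, uniform on the normal circle in 3D).
sample_normal_directions <- function(tangent) {
  n <- nrow(tangent)
  d <- ncol(tangent)
  if (d == 2L) {
    normal <- cbind(-tangent[, 2L], tangent[, 1L])
    normal * sample(c(-1, 1), n, replace = TRUE)
  } else {
    ref <- matrix(rep(c(0, 0, 1), each = n), ncol = 3L)
    near_parallel <- abs(tangent[, 3L]) > 0.9
    ref[near_parallel, ] <- matrix(rep(c(1, 0, 0), each = sum(near_parallel)),
                                   ncol = 3L)
    u <- cbind(tangent[, 2L] * ref[, 3L] - tangent[, 3L] * ref[, 2L],
               tangent[, 3L] * ref[, 1L] - tangent[, 1L] * ref[, 3L],
               tangent[, 1L] * ref[, 2L] - tangent[, 2L] * ref[, 1L])
    u <- u / sqrt(rowSums(u^2))
    v <- cbind(tangent[, 2L] * u[, 3L] - tangent[, 3L] * u[, 2L],
               tangent[, 3L] * u[, 1L] - tangent[, 1L] * u[, 3L],
               tangent[, 1L] * u[, 2L] - tangent[, 2L] * u[, 1L])
    phi <- stats::runif(n, 0, 2 * pi)
    u * cos(phi) + v * sin(phi)
  }
}

#' Generate a vessel-anchored synthetic tissue
#'
#' Places anchor cells along vessel polylines (Poisson-distributed count per
#' vessel, uniform by arc length) and non-anchor cells by sampling a vessel
#' point uniformly by arc length, a direction uniformly, and a radial
#' distance from the cell type's configured law, plus Gaussian positional
#' jitter.  The ground truth records each cell's sampled (generating) radial
#' distance and its exact nearest-skeleton distance — the two differ when a
#' cell lands nearer to another vessel than to its generating point.
#' Bit-reproducible given (config, seed).
#'
#' @param config A [synthetic_config()].
#' @param seed Integer RNG seed.
#' @return A list with `cells` (tibble: `cell_id`, `x`, `y`\[, `z`\],
#'   `label`) and `truth` (tibble: `cell_id`, `label`, `law`,
#'   `generating_distance`, `skeleton_distance`; anchors have law
#'   `"anchor"` and generating distance 0).
#' @export
generate_vessel_tissue <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(config$vessels) == 0L) {
    stop("config error: empty vessel skeleton with nonzero anchor density",
         call. = FALSE)
  }
  d <- length(config$extent)
  withr::with_seed(as.integer(seed), {
    # Anchors: Poisson count along total arc length, uniform by arc length.
    total_len <- sum(vapply(config$vessels, function(v) {
      sum(sqrt(rowSums((v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2)))
    }, numeric(1)))
    n_anchor <- stats::rpois(1L, config$anchor_density * total_len)
    apos <- sample_on_skeleton(config$vessels, n_anchor)$points

    coords <- list(apos)
    labels <- list(rep(config$anchor_label, n_anchor))
    gen_d <- list(rep(0, n_anchor))
    laws <- list(rep("anchor", n_anchor))
    for (i in seq_len(nrow(config$cell_types))) {
      ct <- config$cell_types[i, ]
      base <- sample_on_skeleton(config$vessels, ct$n)
      r <- sample_radial_distance(ct$law, ct$param1, ct$param2, ct$n)
      dir <- sample_normal_directions(base$tangent)
      pos <- base$points + dir * r
      if (config$noise_sd > 0) {
        pos <- pos + matrix(stats::rnorm(ct$n * d, sd = config$noise_sd),
                            ncol = d)
      }
      coords <- c(coords, list(pos))
      labels <- c(labels, list(rep(ct$label, ct$n)))
      gen_d <- c(gen_d, list(r))
      laws <- c(laws, list(rep(ct$law, ct$n)))
    }
    pos <- do.call(rbind, coords)
    cells <- tibble::tibble(cell_id = seq_len(nrow(pos)) - 1L,
                            x = pos[, 1L], y = pos[, 2L])
    if (d == 3L) cells$z <- pos[, 3L]
    cells$label <- unlist(labels)
    truth <- tibble::tibble(
      cell_id = cells$cell_id,
      label = cells$label,
      law = unlist(laws),
      generating_distance = unlist(gen_d),
      skeleton_distance = dist_to_skeleton(pos, config$vessels)
    )
    list(cells = cells, truth = truth)
  })
}

#' Generate a tissue with planted neighborhood zones
#'
#' Each configured zone is filled with uniformly placed cells whose labels
#' are drawn from the zone's cell-type mixture; anchor cells arise in every
#' zone through the anchor label's mixture mass.  The zone id per cell is the
#' planted ground truth for neighborhood-recovery experiments.
#'
#' @param config A [synthetic_config()] with `zones` set (>= 1 disjoint
#'   zones).
#' @param seed Integer RNG seed.
#' @return A list with `cells` and `truth` (tibble: `cell_id`, `label`,
#'   `zone`).
#' @export
generate_planted_neighborhoods <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(config$zones) || length(config$zones) == 0L) {
    stop("config error: no zones configured", call. = FALSE)
  }
  d <- length(config$extent)
  withr::with_seed(as.integer(seed), {
    parts <- lapply(seq_along(config$zones), function(zi) {
      zn <- config$zones[[zi]]
      n <- zn$n
      pos <- cbind(stats::runif(n, zn$xmin, zn$xmax),
                   stats::runif(n, zn$ymin, zn$ymax))
      if (d == 3L) {
        pos <- cbind(pos, stats::runif(n, zn$zmin %||% 0,
                                       zn$zmax %||% config$extent[3L]))
      }
      lab <- sample(names(zn$mixture), n, replace = TRUE,
                    prob = as.numeric(zn$mixture))
      list(pos = pos, label = lab, zone = rep(zi, n))
    })
    pos <- do.call(rbind, lapply(parts, `[[`, "pos"))
    cells <- tibble::tibble(cell_id = seq_len(nrow(pos)) - 1L,
                            x = pos[, 1L], y = pos[, 2L])
    if (d == 3L) cells$z <- pos[, 3L]
    cells$label <- unlist(lapply(parts, `[[`, "label"))
    truth <- tibble::tibble(cell_id = cells$cell_id, label = cells$label,
                            zone = unlist(lapply(parts, `[[`, "zone")))
    list(cells = cells, truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard three-zone planted configuration
#'
#' The package's reference planted-neighborhood setting: a 3000 x 1000 um
#' field split into three equal-width zones whose cell-type mixtures are
#' well separated (pairwise total-variation distance >= 0.5) and each
#' contain 10% endothelial (anchor) cells.
#'
#' @param n_cells Total cell count, split equally across zones
#'   (default 10000).
#' @return A [synthetic_config()] with three planted zones.
#' @export
default_planted_config <- function(n_cells = 10000) {
  n_zone <- round(n_cells / 3)
  zones <- list(
    list(xmin = 0, xmax = 1000, ymin = 0, ymax = 1000, n = n_zone,
         mixture = c("endothelial cell" = 0.10, "t cell" = 0.55,
                     "b cell" = 0.25, "epithelial cell" = 0.05,
                     "fibroblast" = 0.05)),
    list(xmin = 1000, xmax = 2000, ymin = 0, ymax = 1000, n = n_zone,
         mixture = c("endothelial cell" = 0.10, "epithelial cell" = 0.60,
                     "fibroblast" = 0.20, "t cell" = 0.05,
                     "b cell" = 0.05)),
    list(xmin = 2000, xmax = 3000, ymin = 0, ymax = 1000, n = n_zone,
         mixture = c("endothelial cell" = 0.10, "fibroblast" = 0.50,
                     "smooth muscle cell" = 0.30, "epithelial cell" = 0.05,
                     "t cell" = 0.05))
  )
  synthetic_config(extent = c(3000, 1000), zones = zones)
}

#' Attach donor / region / condition metadata to a cells table
#'
#' Assigns regions as spatial grid tiles over the table's bounding box and
#' donors as contiguous blocks of tiles, giving `n_donors * n_regions`
#' donor-region groups; a binary condition is assigned per donor.  Optionally
#' assigns subregions as horizontal bands (or one field-wide subregion).
#'
#' @param cells A cells tibble.
#' @param n_donors,n_regions Donor and per-donor region counts (default 8
#'   each, 64 groups).
#' @param seed Integer seed (controls the donor-to-condition assignment).
#' @param condition_levels Two condition labels
#'   (default `c("control", "case")`); half the donors (rounded down) get the
#'   second level.
#' @param subregion_labels Optional character vector: subregions assigned as
#'   equal horizontal bands in `y`; a single label spans the whole field.
#' @return `cells` with `donor_id`, `region`, `condition` (and `subregion`)
#'   columns.
#' @export
attach_metadata <- function(cells, n_donors = 8, n_regions = 8, seed = 1,
                            condition_levels = c("control", "case"),
                            subregion_labels = NULL) {
  stopifnot(n_donors >= 1, n_regions >= 1, length(condition_levels) == 2L)
  n_tiles <- n_donors * n_regions
  n_col <- ceiling(sqrt(n_tiles))
  n_row <- ceiling(n_tiles / n_col)
  ix <- pmin(n_col - 1L, floor((cells$x - min(cells$x)) /
               (diff(range(cells$x)) + 1e-9) * n_col))
  iy <- pmin(n_row - 1L, floor((cells$y - min(cells$y)) /
               (diff(range(cells$y)) + 1e-9) * n_row))
  tile <- pmin(n_tiles - 1L, as.integer(iy * n_col + ix))
  donor_idx <- tile %/% n_regions
  region_idx <- tile %% n_regions
  cells$donor_id <- sprintf("donor%02d", donor_idx + 1L)
  cells$region <- sprintf("region%02d", region_idx + 1L)
  cond <- withr::with_seed(as.integer(seed), {
    flags <- rep(condition_levels[1L], n_donors)
    flags[sample.int(n_donors, n_donors %/% 2L)] <- condition_levels[2L]
    flags
  })
  cells$condition <- cond[donor_idx + 1L]
  if (!is.null(subregion_labels)) {
    nb <- length(subregion_labels)
    band <- pmin(nb - 1L, floor((cells$y - min(cells$y)) /
                   (diff(range(cells$y)) + 1e-9) * nb))
    cells$subregion <- subregion_labels[band + 1L]
  }
  cells
}

#' Simulate donor-level neighborhood-percentage tables
#'
#' Draws donor-level neighborhood percentage vectors from a Dirichlet
#' distribution (so each donor's percentages are non-negative and sum to
#' 100), for two arms of donors.  In the second arm one neighborhood's mean
#' percentage is shifted additively by `shift` points (the remaining
#' neighborhoods absorb the complement proportionally).  Used for power and
#' type-I-error simulations of the donor-level tests.  At the defaults
#' (precision 50, base 30%) the between-donor SD is about 6 percentage
#' points.
#'
#' @param n_per_arm Donors per arm (default 8).
#' @param base Mean percentages per neighborhood, summing to 100
#'   (default `c(30, 30, 20, 20)`).
#' @param shift Additive shift, in percentage points, applied to
#'   `shifted_neighborhood` in arm 2 (default 0 = null).
#' @param shifted_neighborhood Index of the shifted neighborhood (default 1).
#' @param precision Dirichlet precision (sum of concentration parameters,
#'   default 50); larger = less between-donor variability.
#' @param seed Integer RNG seed.
#' @param arm_labels Condition labels for the two arms.
#' @return A long tibble: `donor_id`, `condition`, `neighborhood`
#'   (`"N1"`, ...), `percentage`.
#' @export
simulate_donor_percentages <- function(n_per_arm = 8,
                                       base = c(30, 30, 20, 20),
                                       shift = 0, shifted_neighborhood = 1,
                                       precision = 50, seed,
                                       arm_labels = c("control", "case")) {
  stopifnot(abs(sum(base) - 100) < 1e-8, precision > 0)
  mean2 <- base
  mean2[shifted_neighborhood] <- base[shifted_neighborhood] + shift
  if (mean2[shifted_neighborhood] <= 0 || mean2[shifted_neighborhood] >= 100) {
    stop("shift pushes the mean percentage outside (0, 100)", call. = FALSE)
  }
  others <- setdiff(seq_along(base), shifted_neighborhood)
  mean2[others] <- base[others] * (100 - mean2[shifted_neighborhood]) /
    (100 - base[shifted_neighborhood])

  rdirichlet <- function(n, alpha) {
    g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), ncol = length(alpha),
                byrow = TRUE)
    g / rowSums(g)
  }
  withr::with_seed(as.integer(seed), {
    p1 <- rdirichlet(n_per_arm, base / 100 * precision) * 100
    p2 <- rdirichlet(n_per_arm, mean2 / 100 * precision) * 100
    nb <- paste0("N", seq_along(base))
    tibble::tibble(
      donor_id = rep(sprintf("donor%02d", seq_len(2L * n_per_arm)),
                     each = length(base)),
      condition = rep(rep(arm_labels, each = n_per_arm), each = length(base)),
      neighborhood = rep(nb, times = 2L * n_per_arm),
      percentage = as.vector(t(rbind(p1, p2)))
    )
  })
}

#' Toy crosswalk for synthetic labels
#'
#' A small synthetic crosswalk mapping the labels produced by the synthetic
#' generators into the three-level typology and Cell Ontology terms, so
#' harmonization can be exercised end-to-end without external files.  Also
#' shipped as `inst/extdata/synthetic_toy_crosswalk.csv`.
#'
#' @return A crosswalk tibble (see [read_crosswalk()]).
#' @export
toy_crosswalk <- function() {
  tibble::tribble(
    ~label, ~label_l3, ~label_l2, ~label_l1, ~cl_label, ~cl_id, ~match_level,
    "endothelial cell", "endothelial cell", "endothelial cell", "endothelial",
      "endothelial cell", "CL:0000115", "exactMatch",
    "t cell", "t cell", "t cell", "immune", "T cell", "CL:0000084", "exactMatch",
    "cd8+ t cell", "cd8-positive t cell", "t cell", "immune",
      "CD8-positive, alpha-beta T cell", "CL:0000625", "narrowMatch",
    "b cell", "b cell", "b cell", "immune", "B cell", "CL:0000236", "exactMatch",
    "macrophage", "macrophage", "macrophage", "immune", "macrophage",
      "CL:0000235", "exactMatch",
    "epithelial cell", "epithelial cell", "epithelial cell", "epithelial",
      "epithelial cell", "CL:0000066", "exactMatch",
    "fibroblast", "fibroblast", "fibroblast", "mesenchymal", "fibroblast",
      "CL:0000057", "exactMatch",
    "smooth muscle cell", "smooth muscle cell", "muscle cell", "mesenchymal",
      "smooth muscle cell", "CL:0000192", "exactMatch",
    "neuron", "neuron", "neuron", "neural", "neuron", "CL:0000540",
      "exactMatch",
    "unknown", "unknown", "unknown", "unknown", "cell", "CL:0000000",
      "narrowMatch"
  )
}
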