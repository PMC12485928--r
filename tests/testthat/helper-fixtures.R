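# Fixture builders shared across test files.  Everything is generated in
# code; no binary fixtures.

# A cells tibble from coordinate vectors; cell_id is the 0-based row index.
make_cells <- function(x, y, z = NULL, label) {
  out <- tibble::tibble(cell_id = seq_along(x) - 1L, x = x, y = y)
  if (!is.null(z)) out$z <- z
  out$label <- label
  out
}

# Uniform-random cells in a box with a given number of "anchor"-labelled
# cells, anchors already selected at the original level.
random_cells <- function(n, n_anchor, dim = 2, seed = 1, extent = 1000) {
  withr::with_seed(seed, {
    lab <- sample(c(rep("anchor", n_anchor), rep("other", n - n_anchor)))
    cells <- make_cells(
      x = stats::runif(n, 0, extent),
      y = stats::runif(n, 0, extent),
      z = if (dim == 3) stats::runif(n, 0, extent) else NULL,
      label = lab
    )
  })
  select_anchors(cells, "anchor", level = "original")
}

expect_edges_equal <- function(e1, e2, tol = 1e-9) {
  expect_identical(e1$source_id, e2$source_id)
  expect_identical(e1$anchor_id, e2$anchor_id)
  expect_equal(e1$distance, e2$distance, tolerance = tol)
}

# Write a data frame to a temp CSV and return the path.
tmp_csv <- function(df, name = "fixture.csv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  readr::write_csv(df, path, progress = FALSE)
  path
}

# Two-zone planted configuration with an anchor-dense first zone: zone 1 has
# anchor fraction `dense`, zone 2 `sparse`, with clearly different non-anchor
# mixtures so clustering separates them.
two_zone_config <- function(n1, n2, dense = 0.30, sparse = 0.1125) {
  synthetic_config(extent = c(2000, 1000), zones = list(
    list(xmin = 0, xmax = 400, ymin = 0, ymax = 1000, n = n1,
         mixture = c("endothelial cell" = dense, "t cell" = 0.55,
                     "b cell" = 1 - dense - 0.55)),
    list(xmin = 400, xmax = 2000, ymin = 0, ymax = 1000, n = n2,
         mixture = c("endothelial cell" = sparse,
                     "epithelial cell" = 0.60,
                     "fibroblast" = 1 - sparse - 0.60))
  ))
}
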