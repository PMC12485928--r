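test_that("generators are bit-reproducible and validate their configs", {
  cfg <- synthetic_config()
  a <- generate_vessel_tissue(cfg, 99)
  b <- generate_vessel_tissue(cfg, 99)
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth, b$truth)
  c2 <- generate_vessel_tissue(cfg, 100)
  expect_false(identical(a$cells, c2$cells))

  expect_error(generate_vessel_tissue(
    synthetic_config(vessels = list()), 1), "empty vessel skeleton")
  expect_error(synthetic_config(cell_types = tibble::tibble(
    label = "x", n = 5L, law = "weibull", param1 = 1, param2 = NA)),
    "unknown distance law")
  expect_error(synthetic_config(zones = list(
    list(xmin = 0, xmax = 10, ymin = 0, ymax = 10, n = 5,
         mixture = c("t cell" = 0.6, "endothelial cell" = 0.5)))),
    "sum to 1")
  expect_error(synthetic_config(zones = list(
    list(xmin = 0, xmax = 10, ymin = 0, ymax = 10, n = 5,
         mixture = c("t cell" = 1)))),
    "positive probability")
  expect_error(synthetic_config(zones = list(
    list(xmin = 0, xmax = 10, ymin = 0, ymax = 10, n = 5,
         mixture = c("endothelial cell" = 1)),
    list(xmin = 5, xmax = 15, ymin = 0, ymax = 10, n = 5,
         mixture = c("endothelial cell" = 1)))),
    "overlap")
})

test_that("truth records generating and exact nearest-skeleton distances", {
  cfg <- synthetic_config(anchor_density = 0.2, noise_sd = 0,
    cell_types = tibble::tibble(label = "t cell", n = 500L, law = "fixed",
                                param1 = 30, param2 = NA))
  sim <- generate_vessel_tissue(cfg, 7)
  t_cells <- sim$truth[sim$truth$law == "fixed", ]
  expect_true(all(t_cells$generating_distance == 30))
  # the generating point lies on the skeleton, so the nearest-skeleton
  # distance can never exceed the sampled radial distance
  expect_true(all(t_cells$skeleton_distance <=
                    t_cells$generating_distance + 1e-9))
  expect_true(all(sim$truth$skeleton_distance >= 0))
  # anchors sit on the skeleton
  expect_lt(max(sim$truth$skeleton_distance[sim$truth$law == "anchor"]), 1e-9)
})

test_that("dense anchors recover the fixed and exponential distance laws", {
  # fixed law d = 30, no noise: every edge distance is at most 30 and the
  # median approaches 30 as anchors densify
  cfg_fixed <- synthetic_config(anchor_density = 2, noise_sd = 0,
    cell_types = tibble::tibble(label = "t cell", n = 2000L, law = "fixed",
                                param1 = 30, param2 = NA))
  sim <- generate_vessel_tissue(cfg_fixed, 11)
  cells <- select_anchors(sim$cells, "endothelial cell", level = "original")
  edges <- nearest_anchor_edges(cells, Inf)
  # finite anchor spacing g adds at most ~g^2/(2*30) um beyond the radial 30
  expect_lte(max(edges$distance), 31)
  expect_gt(median(edges$distance), 29.5)
  expect_lte(median(edges$distance), 30 + 0.1)

  # exponential law, scale 20 um: median of measured edges near 20*ln 2
  cfg_exp <- synthetic_config(anchor_density = 2, noise_sd = 0,
    cell_types = tibble::tibble(label = "t cell", n = 3000L,
                                law = "exponential", param1 = 20,
                                param2 = NA))
  sim2 <- generate_vessel_tissue(cfg_exp, 12)
  cells2 <- select_anchors(sim2$cells, "endothelial cell", level = "original")
  med <- median(nearest_anchor_edges(cells2, Inf)$distance)
  expect_lt(abs(med - 20 * log(2)) / (20 * log(2)), 0.1)
})

test_that("planted zone windows converge to the zone mixture", {
  cfg <- synthetic_config(extent = c(2000, 1000), zones = list(
    list(xmin = 0, xmax = 1000, ymin = 0, ymax = 1000, n = 2500,
         mixture = c("endothelial cell" = 0.1, "t cell" = 0.9)),
    list(xmin = 1000, xmax = 2000, ymin = 0, ymax = 1000, n = 2500,
         mixture = c("endothelial cell" = 0.1, "epithelial cell" = 0.9))))
  sim <- generate_planted_neighborhoods(cfg, 3)
  cells <- select_anchors(sim$cells, "endothelial cell", level = "original")
  comp <- knn_neighbor_composition(cells, k = 100, level = "original")
  zone <- sim$truth$zone[match(comp$cell_id, sim$truth$cell_id)]
  m <- composition_matrix(comp)
  # interior anchors (away from the zone boundary) match their mixture
  x <- cells$x[match(comp$cell_id, cells$cell_id)]
  interior1 <- zone == 1 & x < 800
  interior2 <- zone == 2 & x > 1200
  dev1 <- abs(m[interior1, "t cell"] - 0.9)
  dev2 <- abs(m[interior2, "epithelial cell"] - 0.9)
  expect_lt(mean(dev1), 0.03)
  expect_lt(mean(dev2), 0.03)
  # the vast majority of interior windows sit within 0.1 of their mixture
  expect_lt(stats::quantile(dev1, 0.95), 0.1)
  expect_lt(stats::quantile(dev2, 0.95), 0.1)
})

test_that("single-zone tissue yields no spurious composition structure", {
  cfg <- synthetic_config(extent = c(1000, 1000), zones = list(
    list(xmin = 0, xmax = 1000, ymin = 0, ymax = 1000, n = 3000,
         mixture = c("endothelial cell" = 0.1, "t cell" = 0.45,
                     "b cell" = 0.45))))
  sim <- generate_planted_neighborhoods(cfg, 19)
  cells <- select_anchors(sim$cells, "endothelial cell", level = "original")
  comp <- knn_neighbor_composition(cells, k = 50, level = "original")
  model <- cluster_compositions(comp, n_clusters = 4, seed = 20)
  # over-clustered noise splits along sampling fluctuations, but the merge
  # step recognizes the clusters as one neighborhood
  mm <- suggest_merges(model, comp, cells)
  expect_equal(dplyr::n_distinct(unname(mm)), 1L)
})

test_that("metadata attachment produces the donor x region design", {
  cells <- withr::with_seed(6, make_cells(runif(4000, 0, 1000),
                                          runif(4000, 0, 1000),
                                          label = "t cell"))
  out <- attach_metadata(cells, n_donors = 8, n_regions = 8, seed = 2,
                         subregion_labels = c("mucosa", "submucosa"))
  expect_equal(dplyr::n_distinct(out$donor_id), 8L)
  expect_equal(dplyr::n_distinct(paste(out$donor_id, out$region)), 64L)
  expect_equal(sort(unique(out$condition)), c("case", "control"))
  # condition is constant within donor
  expect_true(all(tapply(out$condition, out$donor_id,
                         dplyr::n_distinct) == 1L))
  expect_setequal(unique(out$subregion), c("mucosa", "submucosa"))
})

test_that("simulated donor percentage tables are compositional with the injected shift", {
  d <- simulate_donor_percentages(n_per_arm = 8, shift = -10, seed = 31)
  sums <- tapply(d$percentage, d$donor_id, sum)
  expect_equal(as.numeric(sums), rep(100, 16), tolerance = 1e-9)
  expect_equal(nrow(d), 16 * 4)
  # arm means reflect the shift direction on the first neighborhood
  m <- tapply(d$percentage[d$neighborhood == "N1"],
              d$condition[d$neighborhood == "N1"], mean)
  expect_lt(m[["case"]], m[["control"]])
})
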