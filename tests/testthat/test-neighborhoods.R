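test_that("composition rows are label fractions over the k nearest cells", {
  # all cells share one label: every row is one-hot
  cells <- random_cells(60, 10, seed = 2)
  cells$label_l3 <- "only type"
  comp <- knn_neighbor_composition(cells, k = 5, level = "l3")
  expect_equal(unname(composition_matrix(comp)[, "only type"]),
               rep(1, sum(cells$is_anchor)))

  # 30-cell toy, one anchor, k = 4: matches sort-by-distance oracle
  toy <- withr::with_seed(9, make_cells(
    runif(30, 0, 100), runif(30, 0, 100),
    label = sample(c("t cell", "b cell", "epithelial cell"), 30, TRUE)))
  toy$label[1] <- "anchor"
  toy <- select_anchors(toy, "anchor", level = "original")
  comp <- knn_neighbor_composition(toy, k = 4, level = "original")
  d <- sqrt((toy$x - toy$x[1])^2 + (toy$y - toy$y[1])^2)
  nearest4 <- toy$label[order(d)[2:5]]
  oracle <- table(factor(nearest4, levels = sort(unique(toy$label)))) / 4
  expect_equal(composition_matrix(comp)[1, ], c(unclass(oracle)))

  # rows always sum to 1
  expect_equal(rowSums(composition_matrix(comp)), stats::setNames(1, "0"))
  expect_error(knn_neighbor_composition(toy, k = 30, level = "original"),
               "size error")
})

test_that("column marginals equal label frequencies among counted neighbors", {
  cells <- random_cells(400, 40, seed = 31)
  cells$label_l3 <- withr::with_seed(32,
    sample(c("a", "b", "c"), 400, TRUE, prob = c(0.5, 0.3, 0.2)))
  k <- 10
  comp <- knn_neighbor_composition(cells, k = k, level = "l3")
  m <- composition_matrix(comp)
  expect_true(all(m >= 0))
  expect_equal(rowSums(m), stats::setNames(rep(1, nrow(m)), rownames(m)),
               tolerance = 1e-12)
  # recount neighbors exhaustively for a sample of anchors
  anchor_rows <- which(cells$is_anchor)
  for (i in c(1, 11, 25)) {
    a <- anchor_rows[i]
    d <- sqrt((cells$x - cells$x[a])^2 + (cells$y - cells$y[a])^2)
    d[a] <- Inf
    nb <- order(d)[1:k]
    expect_equal(m[i, "a"], mean(cells$label_l3[nb] == "a"))
  }
})

test_that("k-means clustering is reproducible and separates planted archetypes", {
  skip_if_not_installed("mclust")
  # two archetype zones separated by a 500 um empty gap: windows never blend
  gap_cfg <- synthetic_config(extent = c(2500, 1000), zones = list(
    list(xmin = 0, xmax = 1000, ymin = 0, ymax = 1000, n = 600,
         mixture = c("endothelial cell" = 0.3, "t cell" = 0.55,
                     "b cell" = 0.15)),
    list(xmin = 1500, xmax = 2500, ymin = 0, ymax = 1000, n = 600,
         mixture = c("endothelial cell" = 0.3, "epithelial cell" = 0.6,
                     "fibroblast" = 0.1))))
  sim <- generate_planted_neighborhoods(gap_cfg, seed = 5)
  cells <- select_anchors(sim$cells, "endothelial cell", level = "original")
  comp <- knn_neighbor_composition(cells, k = 20, level = "original")
  m1 <- cluster_compositions(comp, n_clusters = 2, seed = 42)
  m2 <- cluster_compositions(comp, n_clusters = 2, seed = 42)
  expect_identical(m1$assignments, m2$assignments)

  truth <- sim$truth$zone[match(comp$cell_id, sim$truth$cell_id)]
  ari <- mclust::adjustedRandIndex(m1$assignments$cluster, truth)
  expect_equal(ari, 1)

  expect_error(cluster_compositions(comp[1:3, ], n_clusters = 5, seed = 1),
               "size error")
})

test_that("merge maps compose onto assignments with additive sizes", {
  asg <- tibble::tibble(cell_id = 0:16,
                        cluster = c(rep(0L, 10), rep(1L, 7)),
                        neighborhood = as.character(c(rep(0L, 10), rep(1L, 7))))
  model <- as_nbhd_model(asg)

  # identity map leaves labels equal to clusters
  ident <- merge_clusters(model, c(`0` = "0", `1` = "1"))
  expect_equal(tidy(ident)$neighborhood, as.character(asg$cluster))

  # {0 -> A, 1 -> A} with sizes 10 and 7 gives A 17 anchors
  merged <- merge_clusters(model, c(`0` = "A", `1` = "A"))
  expect_equal(sum(tidy(merged)$neighborhood == "A"), 17L)

  expect_error(merge_clusters(model, c(`0` = "A")), "mapping error.*1")

  # 20 clusters merged under a map with 11 distinct targets -> 11 neighborhoods
  asg20 <- tibble::tibble(cell_id = 0:39, cluster = rep(0:19, each = 2L),
                          neighborhood = "x")
  map11 <- stats::setNames(sprintf("nb%02d", (0:19) %% 11), as.character(0:19))
  m20 <- merge_clusters(as_nbhd_model(asg20), map11)
  expect_equal(dplyr::n_distinct(tidy(m20)$neighborhood), 11L)
  expect_equal(glance(m20)$n_neighborhoods, 11L)
})

test_that("suggest_merges joins similar co-localized clusters and leaves distinct ones", {
  # two interleaved clusters with identical compositions -> one neighborhood
  sim <- generate_planted_neighborhoods(
    synthetic_config(extent = c(1000, 1000), zones = list(
      list(xmin = 0, xmax = 1000, ymin = 0, ymax = 1000, n = 800,
           mixture = c("endothelial cell" = 0.2, "t cell" = 0.8)))),
    seed = 8)
  cells <- select_anchors(sim$cells, "endothelial cell", level = "original")
  comp <- knn_neighbor_composition(cells, k = 15, level = "original")
  model <- cluster_compositions(comp, n_clusters = 2, seed = 3)
  mm <- suggest_merges(model, comp, cells)
  expect_equal(dplyr::n_distinct(unname(mm)), 1L)

  # well-separated archetypes over-clustered to 4 -> suggestion collapses to 2
  sim2 <- generate_planted_neighborhoods(two_zone_config(800, 800, sparse = 0.30),
                                         seed = 12)
  cells2 <- select_anchors(sim2$cells, "endothelial cell", level = "original")
  comp2 <- knn_neighbor_composition(cells2, k = 20, level = "original")
  model2 <- cluster_compositions(comp2, n_clusters = 4, seed = 13)
  mm2 <- suggest_merges(model2, comp2, cells2)
  expect_equal(dplyr::n_distinct(unname(mm2)), 2L)
  # merged neighborhoods correspond to the planted zones
  final <- tidy(merge_clusters(model2, mm2))
  truth <- sim2$truth$zone[match(final$cell_id, sim2$truth$cell_id)]
  # boundary windows genuinely mix the two zones, so agreement is high but
  # not perfect
  expect_gte(suppressWarnings(mclust::adjustedRandIndex(final$neighborhood,
                                                        truth)), 0.9)
})

test_that("radial composition at the model window reproduces the clustering matrix", {
  sim <- generate_planted_neighborhoods(two_zone_config(500, 500), seed = 17)
  cells <- select_anchors(sim$cells, "endothelial cell", level = "original")
  k <- 25
  comp <- knn_neighbor_composition(cells, k = k, level = "original")
  model <- cluster_compositions(comp, n_clusters = 3, seed = 2)
  rad <- radial_composition(cells, model, window_sizes = c(5, k),
                            level = "original")

  per_nb <- dplyr::inner_join(comp, neighborhood_labels(model),
                              by = "cell_id") |>
    tidyr::pivot_longer(-c("cell_id", "neighborhood"),
                        names_to = "cell_type", values_to = "fraction") |>
    dplyr::group_by(neighborhood, cell_type) |>
    dplyr::summarise(fraction = mean(fraction), .groups = "drop")
  at_k <- dplyr::arrange(rad[rad$window == k,
                             c("neighborhood", "cell_type", "fraction")],
                         neighborhood, cell_type)
  expect_equal(as.data.frame(at_k), as.data.frame(per_nb))
})

test_that("anchor-type enrichment hits 0 and 1 in the degenerate geometries", {
  # lone anchors far apart, k small: windows contain only non-anchors -> 0
  cells <- make_cells(c(0, 1, 2, 1000, 1001, 1002),
                      c(0, 0, 0, 0, 0, 0),
                      label = c("anchor", "o", "o", "anchor", "o", "o"))
  cells <- select_anchors(cells, "anchor", level = "original")
  comp <- knn_neighbor_composition(cells, k = 2, level = "original")
  model <- as_nbhd_model(tibble::tibble(cell_id = comp$cell_id, cluster = 1L,
                                        neighborhood = "all"))
  expect_equal(ec_enrichment(comp, model)$ec_enrichment, 0)

  # tight anchor triplets: windows of pure anchors -> 1
  pure <- make_cells(c(0, 1, 2, 500, 501, 502), rep(0, 6), label = "anchor")
  pure <- select_anchors(pure, "anchor", level = "original")
  comp2 <- knn_neighbor_composition(pure, k = 2, level = "original")
  model2 <- as_nbhd_model(tibble::tibble(cell_id = comp2$cell_id, cluster = 1L,
                                         neighborhood = "all"))
  expect_equal(ec_enrichment(comp2, model2)$ec_enrichment, 1)

  # hand-counted tally: anchor at 0 has neighbors {1: anchor, 2: other}
  mix <- make_cells(c(0, 1, 2), c(0, 0, 0), label = c("anchor", "anchor", "o"))
  mix <- select_anchors(mix, "anchor", level = "original")
  comp3 <- knn_neighbor_composition(mix, k = 2, level = "original")
  model3 <- as_nbhd_model(tibble::tibble(cell_id = comp3$cell_id, cluster = 1L,
                                         neighborhood = "all"))
  # anchor 0 sees {anchor, other}; anchor 1 sees {anchor, other}
  expect_equal(ec_enrichment(comp3, model3)$ec_enrichment,
               mean(c(1 / 2, 1 / 2)))
})

test_that("subregion-normalized enrichment recovers a planted 2x anchor-dense zone", {
  sim <- generate_planted_neighborhoods(two_zone_config(1500, 6000), seed = 23)
  cells <- select_anchors(sim$cells, "endothelial cell", level = "original")
  cells$donor_id <- "donor01"
  cells$subregion <- "tissue"
  comp <- knn_neighbor_composition(cells, k = 30, level = "original")
  # neighborhoods fixed from the planted truth (zone of each anchor)
  zone <- sim$truth$zone[match(comp$cell_id, sim$truth$cell_id)]
  model <- as_nbhd_model(tibble::tibble(cell_id = comp$cell_id,
                                        cluster = zone,
                                        neighborhood = paste0("zone", zone)))
  enr <- normalized_ec_enrichment(cells, comp, model)
  # zone 1 planted at 0.30 anchors vs 0.15 overall
  f1 <- enr$fold_change[enr$neighborhood == "zone1"]
  expect_lt(abs(f1 - 2), 0.25)
  expect_false(any(enr$flagged))
  expect_error(normalized_ec_enrichment(dplyr::select(cells, -subregion),
                                        comp, model),
               "schema error.*subregion")
})

test_that("neighborhood percentages sum to 100 per group with completed zeros", {
  cells <- make_cells(1:10, 1:10, label = "anchor")
  cells$region <- rep(c("r1", "r2"), each = 5)
  model <- as_nbhd_model(tibble::tibble(
    cell_id = 0:9,
    cluster = c(1L, 1L, 1L, 2L, 2L, rep(2L, 5)),
    neighborhood = c(rep("A", 3), rep("B", 2), rep("B", 5))))
  pct <- neighborhood_percentages(model, cells, "region")
  expect_equal(pct$percentage[pct$region == "r1" & pct$neighborhood == "A"], 30 / 0.5)
  # group with 3 of 10 anchors in A when all anchors counted together
  all_pct <- neighborhood_percentages(
    model, dplyr::mutate(cells, g = "all"), "g")
  expect_equal(all_pct$percentage[all_pct$neighborhood == "A"], 30)
  sums <- tapply(pct$percentage, pct$region, sum)
  expect_equal(as.numeric(sums), c(100, 100))
  # zero row completed for neighborhoods absent from a group
  expect_equal(pct$percentage[pct$region == "r2" & pct$neighborhood == "A"], 0)

  # single neighborhood: 100% everywhere
  one <- as_nbhd_model(tibble::tibble(cell_id = 0:9, cluster = 1L,
                                      neighborhood = "only"))
  p1 <- neighborhood_percentages(one, cells, "region")
  expect_equal(p1$percentage, c(100, 100))

  # a group whose cells are all non-anchors triggers the omission warning
  extra <- dplyr::bind_rows(cells,
    tibble::tibble(cell_id = 100L, x = 1, y = 1, label = "o", region = "r3"))
  expect_warning(neighborhood_percentages(model, extra, "region"),
                 "zero anchor")
})
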