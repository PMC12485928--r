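---
title: "Anchor-cell distance graphs and neighborhoods: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-cell distance graphs and neighborhoods: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellanchor)
library(dplyr)
```

## The model

Spatial single-cell assays deliver, per dataset, a table of cell centroids
(x, y, optionally z, in µm after pixel-size scaling) with a cell-type label
per cell. `cellanchor` organizes the analysis of such tables around an
**anchor cell type** — by default an endothelial-cell (EC) category, because
proximity to blood vasculature shapes nutrient access, immune surveillance
and niche identity for most other cell types.

Two complementary summaries are built from the same table:

1. **The distance graph.** For every non-anchor cell, the Euclidean
   distance to its nearest anchor cell defines one edge, retained when it
   does not exceed a maximum distance threshold (default 200 µm).  The
   distribution of these distances, summarized per cell type and grouping
   (region, donor, condition), carries the "how far from vasculature does
   this cell type live" signal: median, quartiles, IQR, and the coefficient
   of variation CV = 100·sd/mean (sample sd, reported in percent; CV 0
   means no variation).

2. **Anchor-centric neighborhoods.** For every anchor cell, the k nearest
   cells (default k = 50, any type, the center excluded) define a
   composition vector — the fraction of each cell-type label in the
   window.  k-means over these simplex vectors (default 20 initial
   clusters) followed by a merge of compositionally similar, spatially
   co-localized clusters yields recurring microenvironment classes.  A
   radial analysis recomputes composition over concentric KNN windows
   (defaults 5, 10, 30, 50, 100, 300 cells) to probe scale dependence, and
   EC enrichment per neighborhood — the mean fraction of anchor-type cells
   in member windows — is normalized per donor by the anchor fraction of
   the enclosing tissue subregion, giving a fold change interpretable as
   "anchor-denser than its subregion average" when above 1.

Labels are harmonized before either step through a three-level typology
crosswalk: the original free-text label maps to L3 (most specific), L2, and
L1 (most general, exactly eight categories: endothelial, epithelial,
hematopoietic precursor, immune, mesenchymal, neural, mixed
immune/epithelial, unknown), each with a Cell Ontology term and a match
level (`exactMatch` or `narrowMatch`).  Matching is on normalized labels
(lower-cased, whitespace-squished), so crosswalk files may use any casing;
deeper format variation (hyphenation, synonyms) must be resolved in the
crosswalk itself.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `max_distance` | 200 µm | inclusive edge-retention threshold |
| `pixel_size` | 1 µm/pixel | coordinate scaling at load time |
| `k` | 50 cells | neighborhood window size |
| `n_clusters` | 20 | initial k-means clusters, merged afterwards |
| `window_sizes` | 5–300 cells | radial analysis windows |
| `level` | l3/l1 | typology level for composition / anchor matching |

The threshold comparison is **inclusive** (distance ≤ 200 µm retained);
"within a threshold" admits either reading, and inclusivity is frozen so
outputs are bit-stable.  Windows are KNN-defined, not metric radii, and the
center anchor is excluded from its own window while other anchor-type cells
do count — EC fractions inside EC neighborhoods are meaningful quantities.

## Numerical choices

- **Exact nearest neighbors.**  Edges and windows use a KD-tree
  (`RANN::nn2`, `eps = 0`, exact).  Distance ties are broken in favor of
  the lowest anchor `cell_id` by rescanning near-tied queries, so output is
  deterministic and order-independent.  An exhaustive all-pairs scan
  (`brute_force_nearest()`) ships as a verification oracle; the test suite
  checks equivalence on over a hundred random 2D/3D instances.
- **Quartiles** use linear interpolation on sorted values
  (`stats::quantile` type 7, the default of mainstream numeric stacks);
  **CV** uses the sample (n−1) standard deviation.  Both conventions are
  frozen for reproducibility rather than derived from a stated standard.
- **k-means** runs on raw fraction vectors — no standardization, since all
  features are fractions on a common scale — with k-means++ seeding, 10
  restarts keeping the lowest total within-cluster sum of squares, and
  Lloyd iterations run to a fixed point (`iter.max = 100`).  Everything is
  seeded; the same `(matrix, seed)` gives bitwise-identical assignments.
- **Merging is user-driven.**  The published workflows merged
  over-clustered solutions by judgment (e.g. 20 initial clusters down to 11
  neighborhoods); `merge_clusters()` therefore takes an explicit map, and
  `suggest_merges()` only proposes one.  The suggestion is agglomerative:
  repeatedly fuse the most cosine-similar pair of groups among spatially
  co-localized pairs, recomputing the merged centroid, so dissimilar groups
  cannot fuse through a chain of intermediates.  Its thresholds
  (cosine ≥ 0.9, co-occurrence ≥ 0.2 within 10 anchor-neighbors) are tool
  parameters, not biological claims; `n_target` mirrors the "merge down to
  a known count" judgment.
- **Degenerate inputs.**  Zero anchors yield empty outputs with a warning,
  not an error; paired tests with zero-variance nonzero differences are
  reported as degenerate (infinite t, p → 0) rather than crashing; groups
  with fewer than two donors, constant covariates, or missing pairing
  raise named errors.
- **Statistics.**  The unpaired donor test defaults to Welch's form (the
  safer modern default when only "unpaired t-test" is specified), with
  `var_equal = TRUE` available for exact pooled-variance replication.  All
  tests are two-sided; no multiple-testing correction is applied by
  default, but a Benjamini–Hochberg column is always emitted.  Donors are
  the replicates: per-region percentages are averaged within donor before
  any test.

## What the synthetic generator emulates — and what it does not

`generate_vessel_tissue()` emulates the one structural assumption behind
the distance graph: cell types sited at characteristic distances from
vessel-like structures.  Anchors are placed along polyline skeletons
(Poisson by arc length); non-anchor cells take a vessel point uniform by
arc length, a radial distance from a per-type law (fixed, uniform annulus,
or exponential), and a direction **normal to the vessel**, plus small
Gaussian jitter (2 µm default).  The normal placement makes the configured
law the law of the cell's distance to the skeleton, so measured
nearest-anchor distances converge to it as anchors densify — e.g. an
exponential law of scale 20 µm yields a measured median near
20·ln 2 ≈ 13.86 µm.  The truth table stores both the sampled generating
distance and the exact nearest-skeleton distance, which differ when a cell
lands nearer another vessel.

`generate_planted_neighborhoods()` emulates the structure behind
neighborhood clustering: disjoint spatial zones with distinct cell-type
mixtures (each containing anchors).  The reference configuration
(`default_planted_config()`) plants three zones of ~3,333 cells each in a
3000 × 1000 µm field with pairwise total-variation distance ≥ 0.5 between
mixtures and 10% ECs per zone — separation strong enough that the full
pipeline (k = 50, 20 clusters, merge to 3) recovers the zones at adjusted
Rand index ≥ 0.9, which is the suite's headline recovery property.

For donor-level statistics, `simulate_donor_percentages()` draws
per-donor neighborhood-percentage vectors from a Dirichlet distribution
(precision 50, i.e. ~6 percentage points of between-donor SD at a 30%
neighborhood — a realistic donor-to-donor spread), with an additive shift
on one neighborhood in one arm; 8 donors per arm and a −10-point shift
give about 85% power, and the null gives a type-I error near the nominal
0.05.  These conditions were set once from what a small human cohort
plausibly looks like, not adjusted to outcomes.

None of this makes the synthetic tissue biologically realistic: vessels do
not branch or follow flow constraints, zone boundaries are sharp
rectangles, cell types are independent marks rather than interacting
populations, and counts do not match any real study.  Passing tests
therefore show the *computations* are correct and the pipeline recovers
*known* structure of the assumed form — not that real tissues contain such
structure, nor that the merge judgment on real data is automatic.

## Problem sizes in the test suite

Unit fixtures run at 10²–10³ cells.  The headline experiments use the
scales at which their guarantees are stated: planted recovery at 10,000
cells (~1,000 anchors), distance-law recovery at 5,000 cells with dense
anchors, enrichment nulls at 10,000 cells, calibration at 1,000 null and
200 alternative cohort simulations, and pipeline determinism at 20,000
cells through the command-line surface.

## Worked example

```{r example}
sim <- generate_planted_neighborhoods(default_planted_config(4000), seed = 1)
cells <- sim$cells |>
  apply_crosswalk(toy_crosswalk()) |>
  select_anchors("endothelial", level = "l1")

edges <- nearest_anchor_edges(cells, max_distance = 200)
summarize_distances(edges, cells, level = "l3")

comp <- knn_neighbor_composition(cells, k = 50, level = "l3")
model <- cluster_compositions(comp, n_clusters = 20, seed = 2)
model <- merge_clusters(model, suggest_merges(model, comp, cells, n_target = 3))
glance(model)
head(tidy(model))
```

## Known limitations

- The crosswalk must be supplied (or the bundled synthetic one used); no
  ontology service is queried and no mapping is inferred from markers.
- Serial-section stacks are treated as independent 2D tables unless a true
  z coordinate is present.
- Distances are Euclidean point-to-point; geodesic or within-tissue path
  distances, distances to vessel outlines, and k > 1 nearest anchors are
  out of scope.
- The cohort module fits no hierarchical models; donors are independent
  replicates and region structure enters only through averaging.
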