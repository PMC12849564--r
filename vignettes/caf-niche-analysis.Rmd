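---
title: "Methods: spatial niche analysis of CAF substates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial niche analysis of CAF substates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cafniche)
```

# Overview

`cafniche` reconstructs the spatial architecture of the tumor
microenvironment from segmented multiplex immunohistochemistry (mIHC) data.
The pipeline has five stages, each usable on its own:

1. **Phenotyping** — per-cell marker mean intensities are gated into
   phenotypes with a fixed hierarchical scheme (`classify_cells()`).
2. **Neighborhoods** — a raster lattice samples the tissue; each lattice
   point is summarized by the phenotype composition of the cells within a
   50 µm radius (`compute_neighborhoods()`).
3. **Regions** — neighborhood compositions are clustered into tissue
   regions with a self-organizing map (SOM) whose codebook is
   meta-clustered by Ward linkage; the number of regions is guided by the
   Davies-Bouldin index (`cluster_regions()`).
4. **Interactions** — shared borders between regions on the label raster
   are converted into a directed percentage matrix and thresholded into a
   region-adjacency graph (`interaction_matrix()`, `threshold_graph()`).
5. **Spatial statistics** — pseudo-space composition gradients
   (`pseudospace()`), censored nearest-neighbor distances to vessels,
   immune and tumor cells (`nearest_distances()`), per-sample composition
   summaries and Wilcoxon rank-sum comparisons.

Because no public per-cell dataset accompanies the design this package
implements, a first-class synthetic generator (`niche_architecture()`)
plants the niche architecture reported for early- (neoplasia) and
late-stage (carcinoma) mammary tumors with full ground truth, and the test
suite validates every stage as a planted-architecture recovery problem.

# The phenotyping model

Cells carry mean intensities for PDGFRα (matrix CAFs), MCAM (vascular
CAFs), α-SMA (myofibroblastic states), CD31 (endothelium), CD45 (immune),
PanCK (tumor epithelium) and DAPI. Gating is hierarchical and sequential:

* MCAM and PDGFRα are evaluated **jointly** first. Double positives are
  *intermediate CAFs* (this includes triple positives with α-SMA — the
  package treats α-SMA as uninformative once a cell is MCAM+/PDGFRα+).
  Single positives enter the vCAF or mCAF branch and are split by α-SMA
  into the myofibroblastic substate 1 (α-SMA+) or the immunomodulatory
  substate 2 (α-SMA−).
* Remaining cells are tested sequentially: CD31 → endothelial, CD45 →
  immune, PanCK → tumor, and finally α-SMA alone → myofibroblast. The
  CD31 → CD45 → PanCK order is a fixed package convention (the order of a
  sequential gate is not fully determined by the published description);
  consequently a CD31+/MCAM+ cell is called vCAF, because the CAF branch
  runs first.
* Anything else is *unclassified*, flagged, and ignored by every
  downstream computation.

Interactively trained per-marker classifiers are replaced by per-marker
thresholds with pluggable calibration. The default (`"gmm"`) fits a
2-component Gaussian mixture to log intensities and places the threshold
at the equal-posterior crossing, solved in closed form from the fitted
parameters; a fixed-quantile alternative exists for markers where the
mixture assumption is poor. Thresholding preserves the logic of the gating
scheme while being reproducible and testable.

# Neighborhoods and regions

`make_grid()` builds an axis-aligned lattice over the cells' bounding box
padded by the neighborhood radius; the default pitch equals the radius
(50 µm), giving overlapping neighborhoods. Neighborhood membership uses
the closed ball (distance ≤ r). Counting is lattice-indexed and agrees
exactly with brute-force distance checking (this is asserted in the test
suite on random instances).

Region clustering operates on **fraction-normalized** compositions by
default in the package's own workflows. Raw counts are supported and
mirror the convention of upstream interactive tools, but fractions are the
recommended input: with raw counts every tissue-margin neighborhood is a
scaled-down copy of its region's profile, which smears each cluster along
a ray through the origin and degrades both the SOM meta-clustering and the
Davies-Bouldin selection.

The SOM is a batch map (default 10 × 10 nodes, 60 iterations) on
per-feature z-scored data. The neighborhood radius anneals linearly from
half the grid diagonal to a hard-assignment (Lloyd) refinement over the
last fifth of training, so the final codebook vectors sit at local data
centroids; batch updates make the fit independent of row order and fully
reproducible from the seed. Codebook vectors are then meta-clustered by
Ward linkage **weighted by node occupancy** (`hclust(ward.D, members = )`
on squared distances): unweighted Ward lets codebook nodes that summarize
only a handful of border neighborhoods claim tree branches before real
regions separate.

Two filters keep noise out of the model: empty neighborhoods are always
excluded (they would otherwise form a spurious zero-composition region),
and *sparse* neighborhoods — fewer cells than 40% of the median non-empty
neighborhood count by default — are excluded from fitting because their
composition fractions are Poisson-noise dominated. Both remain in the
spatial map as background.

For every candidate k (default 2–15) the Davies-Bouldin index is computed
on the z-scored neighborhood vectors:

$$\mathrm{DB} = \frac{1}{k}\sum_i \max_{j \ne i}
  \frac{\sigma_i + \sigma_j}{\lVert c_i - c_j \rVert},$$

with cluster centroids $c$ and mean within-cluster centroid distances
$\sigma$. The selected k is the argmin (ties to the smaller k, for
parsimony) and the full curve is kept on the model object for inspection
(`autoplot()` plots it). The index can also be computed on the codebook
nodes (`db_on = "nodes"`); neighborhoods are the default because they are
the objects the regions are meant to partition.

# Border interactions

`region_map()` reshapes the labels onto the lattice. Boundary edges are
8-connected lattice pairs with differing non-background labels (diagonal
contacts count as borders at 50 µm pitch; 4-connectivity is available).
The directed matrix entry P[A, B] is the percentage of A's boundary edges
that touch B, so every row with at least one boundary edge sums to 100.
The undirected niche-adjacency graph retains {A, B} when
max(P[A,B], P[B,A]) reaches the cutoff — 10% is the conventional default
for multiplex images, 5% for in-situ transcriptomics panels. Per-sample
matrices can be averaged element-wise on the union of label sets; regions
missing from a sample contribute flagged zero rows.

# Pseudo-space and distances

`pseudospace()` sorts non-empty neighborhoods by a composition key —
default immune fraction − tumor fraction, descending, with ties broken by
total count then grid index so the ordering is invariant to input row
order — and smooths each phenotype's fraction along the ordering with a
centered moving average (window 5% of neighborhoods, shrinking at the
edges).

`nearest_distances()` computes, per sample, each source cell's Euclidean
distance to the nearest target of each class (immune cells, tumor cells,
vessel tiles), using a bucket grid so only local candidates are scanned.
Distances beyond the censor radius are *flagged censored*, never zeroed or
dropped silently: "within a 10 µm radius" is implemented as a censored
nearest-neighbor distance because reported mean distances exceed what a
hard 10 µm cap could produce. Default profiles use 10 µm (means) and
100 µm (distribution inspection). Per-sample means are taken over
uncensored values; sample-level values feed `wilcoxon_compare()`
(two-sided rank-sum, exact for small tie-free samples, with the
figure-legend star bands). No multiple-comparison correction is applied by
default, matching the per-panel convention of the source analyses.

Vessel annotations (GeoJSON polygons) are subdivided into square tiles —
10 µm side by default, i.e. 100 µm² — whose clipped-shape centroids act as
proxy endothelial "cells". The published tiling description ("10 µm²
tiles") is ambiguous between side and area; the package reads it as side
= 10 µm, the tiling convention of interactive pathology software, and the
literal area reading is available via `tile_side = sqrt(10)`. Tiles
whose clipped area falls below a quarter of a full tile are dropped by
default (or merged into the nearest retained tile).

# The synthetic tissue generator

`generate_tissue()` places cells by thinning a homogeneous Poisson
envelope, so within each planted region the number of cells of a phenotype
is Poisson with mean `density × fraction × area` — count statistics have
an exact noise model. Marker intensities are log-normal per (phenotype,
marker), strictly positive and right-skewed like fluorescence means, with
positive and negative locations separated far beyond their interquartile
ranges (planted separability). Coordinates are µm in image convention
(origin top-left, y down).

`niche_layout()` encodes the reported niche topology procedurally on a
3 × 3 mm field:

* a concentric tumor nest: core; a mid annulus split into a tumor-mid
  sector and a myofibroblastic-CAF *shield* sector so that both touch the
  core; and an endothelial-enriched buffer ring;
* the remaining stroma as vertical stripes — immune-exclusive, mixed
  immune+mCAF2, and mCAF2-exclusive — plus, at early stage only, a
  myofibroblast-exclusive disc and a second endothelial-enriched disc.

The buffer ring guarantees the planted property that immune/mCAF2 regions
never border tumor-enriched regions, while the shield borders the core
directly. The planted adjacency is recorded in the ground truth and the
realized geometry is tested against it.

Archetype compositions (see `builtin_archetypes()`) are qualitative
encodings of the published enrichments — the heatmaps they derive from
print no numbers — chosen under three design rules: (1) the documented
orderings hold (immune-rich archetypes have mCAF2 > mCAF1; late tumor-rich
archetypes have mCAF1 > mCAF2 and vCAF1 > vCAF2; early tumor-rich the
vCAF2/mCAF2-leaning patterns; immune percentage rises from early to late);
(2) every phenotype varies substantially across archetypes, because a
phenotype that is uniformly rare contributes a pure-noise dimension after
z-scoring; (3) related archetypes differ in at least one orthogonal minor
population, not only along one gradient, so that planted clusters are
recoverable at the fixed 50 µm analysis scale. Cell densities
(4500–9000 cells/mm², tumor cores densest) are typical of dense mammary
carcinoma sections and give ≈ 35–70 cells per 50 µm neighborhood.

Vessels are thin rectangular ribbons (80–220 µm long, 12–24 µm wide),
preferentially placed in endothelial-enriched regions (tumor cores are
nearly avascular), lined with a low density of endothelial cells. A
fraction of vascular CAFs within 75 µm of a vessel is repositioned against
the vessel wall at an exponential distance-decay offset capped at 20 µm —
vCAF1 more strongly than vCAF2 — planting the perivascular enrichment that
the distance analysis is expected to recover. The search radius is
deliberately local so that repositioning does not distort region
compositions at the neighborhood scale.

What the generator does *not* emulate: segmentation errors and doublets,
spatial intensity gradients or batch effects, irregular tissue boundaries,
cell-size variation (points, not shapes), and biological gradients within
a region (compositions are piecewise constant). Passing the recovery
suite therefore shows the pipeline is correct and sensitive at realistic
noise levels, not that it is robust to all failure modes of real slides.

# Numerical choices and degenerate inputs

* All randomness flows through explicit integer seeds; cohort samples use
  deterministically derived child seeds.
* Threshold calibration errors out on constant intensity columns, naming
  the marker; fewer than 100 cells is an error.
* `davies_bouldin()` requires ≥ 2 clusters and errors on coincident
  centroids (where the index is undefined).
* Ties in the Davies-Bouldin curve resolve to the smaller k; ties in BMU
  assignment resolve to the first node.
* Empty tile sets and empty edge lists are valid outputs, not errors;
  a region with no boundary edges gets a flagged zero row.
* The problem sizes used by the validation suites — a 3 × 3 mm field at
  default density (≈ 55–60k cells, ≈ 3.7k neighborhoods), 20 seeds per
  stage, 12-sample cohorts for distance analysis — were chosen as the
  smallest sizes at which the planted architecture is comfortably above
  the recovery noise floor.

# Known limitations

* The Davies-Bouldin argmin prefers merging clusters whose separation is
  much smaller than the global scale; on real tissue with strong nested
  structure the curve should be *inspected* (it is retained on the model)
  rather than trusted blindly.
* Shared-border percentages are normalized by each region's own boundary
  (directional); other tools may normalize differently, so absolute
  percentages are not comparable across software, only the thresholded
  graphs are.
* The gating scheme assigns exactly one label per cell; genuinely
  ambiguous multi-lineage signals (e.g. CD45+PanCK+ doublets) follow the
  fixed precedence order rather than being flagged.
* Distances are 2-D section distances, not 3-D tissue distances.
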