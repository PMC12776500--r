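---
title: "Scoring cell-orientation disorganization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cell-orientation disorganization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misalign)
```

## The measurement problem

In a longitudinal section of a developing long bone, growth-plate
chondrocytes are flattened and stacked into columns: the long axis of each
cell lies roughly perpendicular to the bone's proximal-distal axis, and
neighboring cells agree closely in orientation. Planar cell polarity (PCP)
perturbations - for example in Wnt5a signaling - degrade this arrangement.
`misalign` turns segmented cell geometries (QuPath GeoJSON exports or label
masks) into two per-cell statistics that quantify that degradation, and
provides the group-level test used to compare genotypes.

A cell's long axis is *axial*: it has no head or tail, so its angle is only
defined modulo 180 degrees. All angle arithmetic in the package respects
this. The smallest difference between two orientations,

d(a, b) = min(|a - b| mod 180, 180 - |a - b| mod 180),

lies in [0, 90]. For two independent uniformly random orientations, d is
uniform on [0, 90] with mean 45 degrees - the calibration constant that
anchors both scores.

## The two scores

**Global orientation angle (GOA).** For a cell with major-axis angle theta
in an annotation whose proximal-distal axis is at angle alpha,
GOA = d(theta, alpha), in [0, 90]. GOA of 0 means parallel to the
proximal-distal axis, 90 perpendicular. GOA does not measure alignment
*strength* per cell; the width of its population distribution does - narrow
means coherent, broad means disorganized.

**Local misalignment score (LMS).** For cell i with neighbor set N(i)
(all cells within radius r of its centroid), the raw score is
m_i = mean over j in N(i) of d(theta_i, theta_j), in [0, 90], and

LMS_i = 45 - |45 - m_i| = min(m_i, 90 - m_i), in [0, 45].

Because orientations enter only through pairwise differences, LMS is
*exactly* invariant to the reference axis, to global rotation, and to
reflection - the test suite asserts this at 1e-9 degrees. Perfect local
alignment gives 0; a neighborhood with completely random orientations gives
45 in the large-neighborhood limit.

### Why the fold is applied to the mean, and what it costs

The fold could in principle be applied per pair (to each d) or once to the
per-cell mean. Only the per-mean fold satisfies both calibration facts at
once: random neighborhoods average 45 (a per-pair fold of a Uniform[0, 90]
variable would average 22.5) and all scores lie in [0, 45]. The per-mean
fold is therefore the package's definition; the unfolded mean is retained
as `fold_mode = "raw"` for sensitivity analyses, because folding makes
m_i > 45 (e.g. a cell perpendicular to a coherent neighborhood) map back
toward 0.

The fold has a finite-neighborhood cost worth knowing about. With k
neighbors of uniformly random orientation, m_i is approximately normal with
mean 45 and standard deviation 25.98 / sqrt(k) (25.98 = sd of
Uniform[0, 90]), so

E[LMS] = 45 - E|45 - m_i| ~= 45 - 0.798 * 25.98 / sqrt(k).

At k = 15 the expected LMS of a *random* field is ~39.6, not 45; the
45-degree calibration is a law-of-large-numbers statement. Consequences
adopted here:

* The random-calibration check in the acceptance suite uses a 5,000-cell
  field with a 1,000 um radius (thousands of neighbors per cell, fold bias
  < 0.6 degrees), which is the regime where "mean LMS = 45 +- 1" is a
  mathematical fact rather than an approximation.
* In tissue, at 10-20 neighbors, *relative* comparisons (genotype A vs B at
  the same radius and density) are unaffected, but absolute LMS values of
  highly disorganized tissue will sit a few degrees below 45. Compare LMS
  across samples only at matched radius and comparable cell density.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `radius` | 30 | um | neighborhood radius; at typical chondrocyte densities this yields on the order of 10-20 neighbors, enough to average orientation noise without crossing zones. Tune per dataset toward that neighbor count. |
| `min_neighbors` | 1 | cells | below this, LMS is undefined (NA), never 0 or 45; undefined cells are excluded from medians and profiles and their count is reported. |
| `fold_mode` | `"folded"` | - | see above. |
| `pz window` | [0, 400) | um | chondrocytes within this HZ distance are relabeled chondro-PZ; half-open so a cell at exactly 400 um stays a chondrocyte. |
| `edge_margin` | 0 | um | cells with centroids this close to the cartilage boundary are dropped (truncated neighborhoods bias LMS downward in aligned tissue); off by default. |
| `low-anisotropy threshold` | 1.1 | Feret ratio | near-round cells have unstable major axes; they are still scored but flagged, so sensitivity analyses can drop them. |

## Geometry conventions

* Angles: degrees, axial in [0, 180), measured from the +x image axis with
  y increasing downward. Any consistent frame gives identical scores, since
  every statistic is a difference of angles.
* Coordinates are converted to micrometers at read time; every radius and
  threshold is in micrometers.
* Major axis = direction of the maximum Feret (caliper) diameter of the
  convex hull, matching the Feret angle of ImageJ/QuPath workflows. Ties
  (square diagonals) break to the smallest axial angle, and the tying shape
  is flagged low-anisotropy. An ellipse-moment fit
  (`orientation_method = "moment"`) is exposed as a cross-check; note that
  for elongated *rectangles* the max caliper is the diagonal, so the two
  estimators legitimately differ off-ellipse. On edge-traced label-mask
  contours the caliper also feels staircase pixelation (a few degrees at
  ~30-pixel axes), where the moment fit is markedly more stable - the
  round-trip tests quantify both.
* Region membership is decided by centroid containment (even-odd rule),
  which is deterministic for cells straddling a region boundary.
  Containment and absolute shoelace area are well defined even for rings
  with incidental self-intersections, so no geometric "repair" pass is
  needed; rings with fewer than 3 distinct vertices or zero area are
  skipped with a warning.
* Neighbor distance is centroid-to-centroid with an inclusive boundary
  (d <= r), built by a sorted-sweep index that the tests hold equal to the
  brute-force all-pairs rule.
* Label masks: pixel (r, c) covers the unit square [c-1, c] x [r-1, r];
  traced polygons follow pixel edges, so pixel-count areas are exact. Of a
  label split into several components, the largest is kept, with a warning.
* Nucleus-cell pairing: containment first, then nearest centroid, ties to
  the smallest cell id; nuclei inside no cell are excluded and counted.

## The group-level test

Per-cell scores are never treated as independent replicates - the embryo is
the exchangeable unit. For each pair of embryos, the package computes the
first-order 1-D Wasserstein distance between their per-cell score
distributions (exact piecewise quantile-function integral; mean absolute
difference of sorted values for equal sizes). The test statistic is

T = mean D(i, j) over between-group pairs / mean D(i, j) over pooled
same-group pairs,

i.e. Gini's mean difference of each pair set - analogous to an F statistic
but non-parametric and sensitive to both location and dispersion
differences. Significance comes from permuting group labels over embryos.
When the number of distinct assignments C(n, n1) is at most B, all are
enumerated and the p-value is exact (observed assignment included, so
p > 0); otherwise B seeded random permutations with the add-one convention
p = (1 + #exceedances)/(B + 1). Equality with the observed statistic counts
as an exceedance (conservative tie rule).

Exactness has a visible consequence at small n: with 4 + 4 embryos there
are only 35 distinct partitions, so achievable p-values are multiples of
1/35 and the exact size at nominal alpha = 0.05 is 1/35 ~= 0.029 - the test
is conservative, never anti-conservative. The acceptance suite verifies
both properties over 1,000 null cohorts and verifies power > 0.8 for a
+15-degree sigma contrast (wrapped-normal spread 10 vs 25 degrees, 4 + 4
embryos, 200 cells each). The within-group mean pools both groups' pairs;
for balanced designs with equal spread this coincides with averaging
per-group means.

The per-embryo, per-location median table (`summarize_median()`,
`medians.csv`) is exported in the shape mixed-effects models consume;
fitting such models is deliberately out of scope here.

## The synthetic generator

`generate_field()` emulates one cartilage annotation: elliptical cells
(default aspect 2.5, mean area 100 um^2, lognormal 10% area scatter) on a
jittered grid (or minimum-distance uniform placement), a rectangular
Col2-positive domain, and an HZ strip at one edge tagged both `hz` and
`marker:ColX` - so classification, zoning, scoring and testing all have
something real to do. Orientation noise is wrapped-normal on the axial
circle: angles are doubled onto the full circle, normal noise is added,
and the result is wrapped and halved - the standard treatment for axial
data; `estimate_axial_sigma()` inverts it. Defaults (spread 10 degrees
about a vertical proximal-distal axis; mutant-like presets at 25 degrees
or distally graded 12-36 degrees) were chosen once as a realistic
aligned-vs-disorganized contrast and are fixed study conditions, not
fitting knobs.

What the generator does *not* emulate: anisotropic cell shape changes,
density gradients, segmentation errors, column structure (cells are
independently oriented given the field model), or marker intensity noise.
Green tests therefore certify the *statistical machinery* - not that any
particular biological effect size will be detected in real tissue.

Cohorts derive per-field seeds from the master seed with a counter, so
regenerating any one embryo reproduces it exactly.

## Problem sizes used by the checks

The acceptance checks run, from scratch: a 5,000-cell uniform-orientation
field (2,000 x 2,000 um, radius 1,000 um) for the 45-degree calibration;
10^6 randomized neighborhoods (1-50 neighbors) plus adversarial
configurations for the [0, 45] range law and its attained bound; 10^5
uniform orientation pairs for the 45-degree pairwise law; 10^6 randomized
pairs for the [0, 90] GOA range; 1,000 null and 300 alternative cohorts
(2 groups x 4 embryos x 200 cells) for test calibration and power; and
5 noise levels x 20 seeds of 400-cell fields for monotonicity of LMS in
sigma. These sizes make Monte-Carlo error small relative to each stated
tolerance.

## Known limitations

* LMS carries no directional (clockwise/counterclockwise) information and
  no vector-PCP readout; it measures coherence, not polarity sign.
* The folded score is non-monotone above a mean difference of 45 (by
  construction); use `fold_mode = "raw"` if that regime matters.
* GOA requires a user-supplied proximal-distal axis per annotation; for
  cell populations without a meaningful tissue axis (scattered "other"
  cells), GOA is not interpretable even though it is computable.
* HZ distance is straight-line Euclidean distance to the HZ polygon, not
  arc length along the bone axis; for strongly curved elements the two
  differ.
* The permutation test needs at least one within-group embryo pair, and
  its resolution is limited by the number of distinct label assignments.
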