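---
title: "Clustering country-level pre-exam anxiety rates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering country-level pre-exam anxiety rates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anxclust)
library(dplyr)
```

## The problem

PISA 2018 recorded, for 56 countries, the percentage of 15-year-old
students who report anxiety before exams, separately for students with low
and high habitual physical activity. Each country contributes one number
per activity group, on a 0-100 percentage scale. `anxclust` groups
countries with similar anxiety levels by agglomerative hierarchical
clustering, validates the grouping with silhouette and variance-
decomposition metrics, and compares the two activity groups country by
country with Z statistics built from the published standard errors.

The package ships the three published country tables as plain-CSV fixtures
(`anx_fixture()`): the 56 low-activity percentages with their published
five-cluster assignment, the 56 high-activity percentages with their
published four-cluster assignment, and the 16-row paired table of group
means and standard errors. Percentages are the printed values (integers in
the two cluster tables, one decimal in the paired table); no attempt is
made to reconstruct unpublished decimals, because only printed values are
citable ground truth.

## Distances and the clustering engine

With a single feature the Euclidean distance between two countries is the
absolute difference of their percentages; `anx_distances()` also accepts
several feature columns, in which case it is the usual straight-line
distance.

`anx_agglomerate()` implements agglomerative clustering itself rather than
wrapping `stats::hclust`, for two reasons: the merge list, its tie-break
behaviour and the cut semantics are the scientific core of this package
and need to be fully specified; and integer-valued percentages make tied
distances the norm rather than the exception, so an unspecified tie-break
silently changes results. The engine is the nearest-neighbor-chain
algorithm with Lance-Williams distance updates, the standard O(n²) scheme
for the four supported, reducible linkages (Ward, complete, average,
single). Ward uses the variance-increase criterion with the conventional
square-root scaling, so heights are on the scale of the input distances
(for two points at distance 5, the merge height is 5) and directly
comparable to `hclust(..., method = "ward.D2")` and to the common Python
implementations; the test suite checks this equality on tie-free data for
all four linkages.

Two conventions make the dendrogram fully deterministic:

* **Canonical leaf order.** Leaves are processed in C-locale alphabetical
  label order, so the tree is invariant under permutations of the input
  rows (a property the tests verify). A tie-break keyed on record order
  would not be.
* **Tie resolution.** Among equally close candidates the chain prefers its
  current partner and then the earliest cluster in canonical order.

Under these conventions the Ward dendrograms of the two bundled tables,
cut at 20% of the maximum merge height, reproduce the published
five-cluster (low activity) and four-cluster (high activity) country
memberships exactly. That reproduction is what fixed the two free choices
the source tables leave open — the linkage (never stated; Ward is the
natural partner of a variance-based evaluation suite) and the tie
ordering — and it is asserted in the acceptance tests rather than assumed.

## Cutting the tree

`cut_to_k()` undoes the last k−1 merges. `cut_at_fraction()` draws a
horizontal line at `fraction × max(height)` and keeps every merge strictly
below it; the published analyses use `fraction = 0.20`. "Strictly below"
matters at the boundary: at `fraction = 1` the top merge is not below its
own height, so a tree with a unique maximum yields two clusters. The two
cuts agree whenever they produce the same number of clusters (tested).
The default cut fraction 0.20 is corroborated by `sensitivity_analysis()`:
on the bundled tables, fractions 0.15 and 0.25 give the same partitions
(adjusted Rand index 1.0 against the 0.20 partition), matching the
published sensitivity claim.

## Validation metrics

For a partition of n countries into k clusters with values x, cluster
means μ_k and grand mean μ:

* silhouette width s(i) = (b(i) − a(i)) / max(a(i), b(i)), with a(i) the
  mean distance to the rest of i's cluster and b(i) the smallest mean
  distance to another cluster. Singleton clusters get s(i) = 0, the common
  convention, which keeps the mean defined for any partition with k ≥ 2;
  k = 1 is an error because b(i) does not exist.
* WCSS = Σ_k Σ_{i∈C_k} (x_i − μ_k)², with two interpretability
  transforms: the average square distance WCSS/n and the "percentual"
  WCSS √(WCSS/n), a root-mean-square deviation in percentage points.
* BCSS = Σ_k n_k (μ_k − μ)², reported together with its per-cluster
  average BCSS/k, the explained variation BCSS/TSS (where
  TSS = WCSS + BCSS; the identity is enforced to 10⁻⁹ relative and also
  exercised property-style on random data), and the BCSS/WCSS ratio
  (undefined, `NA`, for all-singleton partitions).

Every metric is cross-checked in the tests against an independent
brute-force double-loop oracle on random instances.

One reporting subtlety: for the low-activity table the published text
calls 1,367.33 the BCSS "absolute value", but 96% explained variation and
a 22.10 ratio are only mutually consistent with the *per-cluster average*
(total ≈ 5 × 1,367.33). `quality_report()` therefore always reports both
`bcss_total` and `avg_bcss_per_cluster`. Similarly, the high-activity
average square distance is 632.80 / 56 = 11.3; the 5.52 printed next to it
in the source is a carry-over from the low-activity analysis.

## Choosing the number of clusters

`select_k()` follows a three-step procedure: (1) cut the dendrogram at the
height fraction to get a candidate k from the tree; (2) compute the mean
silhouette for every k in `k_range` (default 2-10) and record the
maximizer, taking the smallest k on ties; (3) report the full dispersion
metrics at the chosen k. The chosen k is the silhouette maximizer, with
the dendrogram candidate reported alongside and a classed warning when the
two disagree.

They genuinely disagree on the bundled tables: the 20% cut gives the
published k (5 and 4), and the published partitions score silhouettes of
0.590 and 0.560, but the silhouette profile computed over dendrogram cuts
is nearly flat and keeps creeping upward as k grows (low activity: 0.600
at k = 6 and 0.605 at k = 10, against 0.590 at k = 5; high activity:
0.578 already at k = 2 and 0.587 at k = 10, against 0.560 at k = 4). On
rounded one-dimensional data many near-equivalent partitions exist, so
the silhouette argmax is not a stable way to pick k here; the package
reports both candidates rather than pretending they coincide.

## Two-group comparisons

`compare_groups()` uses the independent-groups rule
se_diff = √(se_low² + se_high²) — the source never states its formula;
this standard construction reproduces the published OECD-average Z within
rounding (−5.51 vs −5.48) — and the two-sided tiers |z| ≥ 1.96 / 2.58 /
3.29 for p < 0.05 / 0.01 / 0.001 (the last is the "three standard
deviations" rule). Several published per-country Z entries (−43, −39,
−25) are inconsistent with any standard formula and look typographical;
the package recomputes Z from the printed group means and standard errors
and keeps the printed values only as pass-through fixture columns. The
same applies to the published chi-square column: the per-country sample
sizes behind it are not public, so `chi2_two_proportions()` is provided as
a generic Pearson 2×2 test (no continuity correction, flagged when an
expected cell is below 1) but is never used to re-derive that column.

## The synthetic generator

`synthetic_spec()` describes K clusters of country percentages with
normal within-cluster spread, clipped to [0, 100] (clipping, not
resampling: monotone, simple, and adequate for means far from the
bounds), plus a per-country paired low-to-high shift and uniform
per-country standard errors. The defaults emulate the published
low-activity structure: means 41/52/60/67/78 with sizes 8/7/16/16/9
(the five published cluster means and sizes), within-cluster spread 2
percentage points (the published clusters have standard deviations of
about 1.7-2.7), mean shift −3 points (the OECD-average change) with a
3-point spread, and standard errors uniform on [0.5, 4.5] (the published
per-country range). The generator is seeded and bit-reproducible;
`recovery_score()` (adjusted Rand index) scores any estimated partition
against the generating truth, and a property test requires exact recovery
in at least 95 of 100 seeded replicates when cluster separation is at
least 6 generator standard deviations.

What the generator does not emulate: survey weighting, within-country
student-level variance, non-normal within-cluster shapes, and any
dependence between a country's level and its standard error. Passing
recovery tests therefore show that the pipeline is correct on data with
genuinely separated clusters, not that real PISA percentages contain such
clusters.

## Pipeline conventions

`run_analysis()` cuts at the configured fraction (the published workflow),
names clusters by ordering them by descending mean — `H-1`, `H-2`, ... for
clusters above the group grand mean, `L-1`, `L-2`, ... below it (the
published tables use H/L labels inconsistently between text and captions;
this rule is the package's fixed convention) — and reports per-cluster
means both exactly and rounded half-up to integers (a 77.89 mean displays
as 78, matching the published headers). Reports are byte-identical across
runs of the same configuration; the run log records seed, linkage,
fraction and package version, and deliberately contains no timestamps.

## Problem sizes and numerical choices

All bundled analyses are desk-scale: 56 countries per group, distance
matrices of 3,136 entries, dendrograms of 55 merges. The property tests
use random instances of 5-25 points and 100-replicate recovery studies;
the whole suite and the acceptance script each run in well under a minute.
Numerical tolerances: the TSS decomposition is enforced at 10⁻⁹ relative;
oracle comparisons use 10⁻⁹ to 10⁻¹²; dendrogram height monotonicity
allows 10⁻⁸ relative slack for float noise in the Lance-Williams updates.

## Known limitations

* One feature per country is the published setting; multi-feature inputs
  are supported but the canonical tie-break then keys on labels only.
* The silhouette-vs-k profile is computed on dendrogram cuts, not on all
  possible partitions; with rounded 1-D data its argmax is unstable (see
  above).
* Published chi-square values and the handful of inconsistent printed Z
  entries are displayed, never reproduced; the raw microdata needed to
  recompute them is not public.
* Centroid and median linkage are deliberately unsupported: they can
  produce height inversions, which would break the monotone-cut semantics.
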