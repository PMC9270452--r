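---
title: "Methods: quantifying biotic homogenization in binned occurrence records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying biotic homogenization in binned occurrence records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of `faunabeta`: the models
and conventions it implements, the parameters that matter and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical choices made where the underlying methods
literature leaves room.

## The inference problem

Biotic homogenization is a rise through time in the mean compositional
similarity of assemblages — a loss of β diversity. Testing for it in a
fossil/modern record faces two obstacles. First, with a handful of time
bins, a regression of similarity on time has essentially no power and is
hostage to single influential bins. Second, similarity statistics respond to
sampling: the number of sites, their spatial spread, site richness, and
dating error all move the metric without any ecological change. The package
therefore treats the question as a permutation-testing problem on a vetted,
binned incidence record, surrounded by explicit sensitivity analyses.

## Data model and vetting

The unit of observation is a *site*: a georeferenced species list with a
median calibrated age (years BP) or a modern flag. Ingestion enforces
referential integrity across the three input tables and collapses duplicate
incidences. Three cleaning steps precede analysis:

* **Layer merging.** Stratigraphic layers at identical coordinates
  (equality after rounding to 4 decimal places, ≈ 11 m) whose ages fall
  within 500 years are combined: species unioned, age set to the mean of
  the layer ages. Merging is transitive — a ladder of layers each within
  500 yr of the next becomes one site — because any cut inside such a chain
  would be arbitrary. The mean (rather than a pooled median) was chosen for
  the merged age as the natural point estimate for two or three layer dates;
  with 5,000-yr bins the difference is immaterial.
* **Vetting.** Sites must contain ≥ 20 species including at least one
  rodent, one artiodactyl, and one carnivore. This aligns fossil sites with
  the sparsest modern surveys and guarantees body-size and trophic breadth.
  Vetting is idempotent and is applied before any subsetting.
* **Binning.** Bins are half-open on the age axis, `(young_edge, old_edge]`,
  so every old edge is closed and the oldest age (30,000 BP by default)
  falls in the oldest bin. An age exactly at the youngest edge (500 BP)
  belongs to no fossil bin; modern-flagged sites go to the modern bin. Sites
  outside the configuration are dropped with a logged count.

Subset variants reproduce the standard robustness battery: *site* filters
(east of the Rocky Mountains, operationalized as lon ≥ −105°, configurable,
since the front range has no canonical meridian; south of the 49th parallel)
drop whole sites, while *species* filters (excluding extinct species; body
mass strictly > 1 kg or > 5 kg) drop species from every site without
re-vetting — re-vetting would alter the site list between variants and
confound the comparison.

## Similarity metrics

All metrics are computed from the pair counts (`a`, `b`, `c`) and reported
on the similarity orientation. The registry covers Jaccard, the corrected
Forbes index, Sørensen similarity, Simpson similarity (turnover), and the
nestedness component `β_sne = β_sor − β_sim`. Two conventions to note:

* When `a = 0` and `min(b, c) = 0` the Simpson denominator vanishes;
  `β_sim` is defined as 0 (the nested limit), matching common package
  behavior. The case cannot arise for non-empty vetted sites.
* The corrected Forbes index equals 1 for *any* fully nested pair
  (`bc = 0`), not only for identical sites — that is a property of the
  formula, and the test suite asserts it as such.

Multiple-site partitions use the Baselga closed forms over
`Σ min(b_ij, b_ji)`, `Σ max(b_ij, b_ji)` and `Σ S_i − S_T`, and reduce
exactly to the pairwise forms at two sites. Mean pairwise similarity uses
unordered pairs without self-pairs; its SEM is the naive `SD/√n_pairs`,
reported as conventionally plotted even though pairs sharing a site are not
independent — inference never relies on this SEM, only on the null model.

## The site-shuffling null model

One replicate reassigns every site (with its species list intact) to a bin,
uniformly at random without replacement, preserving each bin's site count.
The per-bin statistic (mean pairwise similarity by default; range size and
occupancy use the same machinery) is recomputed per replicate, 1,000 times
by default. The effect size is `(obs − null mean)/null SD`; the 95% band is
the 2.5th/97.5th percentile of the null replicates. Percentiles were chosen
over a normal-theory band because the null distribution of a bin mean over
few sites is visibly skewed; a `band_type = "normal"` flag exposes the
alternative, and the ambiguity (band on the null distribution vs on its
mean) is resolved toward the distribution, the stricter reading. A zero
null SD leaves the effect size undefined (`NA`) and significance is then
judged by the band alone.

Implementation note: the all-sites pairwise similarity matrix is computed
once, so a shuffle replicate is pure index permutation; 1,000 replicates on
a 330-site record take well under a second.

## Sensitivity designs

* **Age error.** Bulk radiocarbon dates carry errors up to ~2,000 yr, so
  each replicate adds `N(0, 2000²)` noise to every fossil age independently
  and re-bins. Modern sites are exempt. A site perturbed outside the
  configuration (including below 0 BP) is dropped for that replicate rather
  than clamped — clamping would pile mass on the youngest bin.
* **Equal-site resampling.** Each replicate draws the poorest bin's site
  count (15 by default) from every bin. The longitudinal-extent variant
  additionally restricts draws to a window whose width is the smallest
  per-bin maximum pairwise longitudinal distance, placed uniformly at
  random over the bin's span (the placement rule is unspecified in the
  methods literature; uniform placement is the least informative choice).
  A window with too few sites is redrawn up to 100 times, then the
  replicate is skipped for that bin with a logged count — bins whose sites
  genuinely span more than the window can therefore return `NA` rather than
  a silently biased subsample.
* **Richness control.** An OLS regression of per-bin mean similarity on
  per-bin pooled richness; a flat, non-significant fit argues the temporal
  trend is not a species-pool artefact. A constant response returns slope 0
  and R² 0 by convention.

## Geography

All planar work happens in a Behrmann (cylindrical equal-area, standard
parallel 30°) projection on a 6,371-km sphere; the projection is exactly
area-preserving, which the tests verify against spherical-excess areas to
0.1%. Great-circle distances use the haversine formula on the same sphere.

**Range size** is the summed convex-hull area of single-linkage point
clusters covering ≥ 95% of a species' sites (≥ 5 distinct sites required).
Clustering cuts the single-linkage dendrogram at *bridge* merges — merges
higher than 3× the median positive merge height — so one diffuse population
center stays whole while centers separated by far more than the typical
nearest-neighbour distance are kept apart and a species occupying two
disjunct regions is not credited with the empty space between them.
Clusters are then retained in order of compactness (mean within-cluster
pairwise distance; lone outliers last) until the coverage level is reached.
Degenerate clusters (< 3 distinct points) contribute zero area; ties break
toward the lowest point index; the procedure is deterministic and invariant
to point order and rigid rotation.

Convex-hull area rises with the number of points sampled from a range, so
bins with more sites are credited with larger hulls at equal true range
size. `mean_range_size(..., equalize_points = k)` subsamples every species
to exactly `k` sites per bin before hulling; between-bin *ratios* of mean
hull area are then unbiased estimates of the true area ratio. The
parameter-recovery experiment in the acceptance suite uses `k = 5` with
uniform (uncluttered) site placement for exactly this reason: with raw
hulls and clustered sites, the recovered multiplier confounds range
inflation with sampling geometry.

**Occupancy** assigns each site to the grid cell containing it (equidistant
boundary points break to the lower cell index) so spatially clustered sites
share one cell and cannot inflate occupancy; a species' occupancy is
occupied cells over total cells. The default grid extent (lon −170…−50,
lat 5…75, 100-km cells) is a continental window chosen by the package; the
cell total of a 100-km Behrmann grid depends entirely on this bounding box,
which published analyses typically leave unstated, so occupancy values are
comparable only within one grid specification.

**Distance decay** is fitted as a binomial-variance log-link GLM
(quasi-likelihood, so non-integer similarities are legitimate) — the
classical exponential decay form for a [0, 1] metric — with OLS available
by flag. **Multivariate dispersion** (mean distance to group centroid in a
principal-coordinates embedding, with Anderson's negative-eigenvalue
correction) delegates to `vegan::betadisper` behind the package's
interface; an all-zero dissimilarity matrix short-circuits to zero
dispersion.

**Space-for-time mapping** computes, for each occupied grid cell, the mean
pairwise Jaccard similarity of the occupied cells within a 1,000-km
great-circle window, optionally subsampling neighbours with probability
proportional to inverse distance. Cells with fewer than two neighbours
return `NA`.

## Climate turnover

The four climate variables (minimum and maximum temperature in °C, actual
evapotranspiration and precipitation in mm/yr) are standardized and
decomposed by a single PCA *pooled across all time slices*, so scores are
comparable between slices — a per-slice PCA would give each slice its own
basis and make between-slice comparisons meaningless; a per-slice mode
exists for sensitivity checks. Turnover per slice is the mean pairwise
Euclidean distance in (PC1, PC2), Euclidean being the natural metric on
orthonormal component scores; slice values are averaged (unweighted) into
the 5,000-yr bins. A zero-variance variable is an error naming the
variable; a singleton slice yields `NA` with a warning.

## The synthetic-data generator

The generator is the package's ground truth. It emulates the deposited
study's shape: ~330 sites in seven bins (25, 15, 30, 45, 60, 88 fossil
sites oldest-to-youngest, 67 modern — matching the published pattern of
sparse glacial and dense Holocene/modern sampling, with the poorest bin at
the 15 sites the resampling design assumes), ~350 species with log-uniform
masses from 5 g to 3,000 kg spread over Rodentia/Artiodactyla/Carnivora/
other in 40/15/15/30 proportions, spatially clustered sites (12 cluster
centers, 150-km scatter), and per-species geodesic-disc ranges (log-normal
radius, median 1,000 km, σ_log = 0.5) detected at probability 0.5 inside
the range. Those range and detection defaults put mean site richness near
40 species so that generated sites pass the ≥ 20-species vetting with
margin rather than by retry luck.

Two signal knobs define experimental conditions. The *extinction pulse*
removes a fraction (0.72) of species above a mass threshold (44 kg) from
every bin whose old edge is at or below the boundary (10,000 BP). *Range
inflation* multiplies range **area** per bin (radius scales by the square
root), so a multiplier of 1.5 emulates a 50% range-size increase; the
study-like configuration used in the analysis scripts and acceptance run is
`(1, 1, 1, 1, 1.5, 1.5, 1.875)` — inflation from the early Holocene with a
further ~25% by modern. With both knobs off the record has no temporal
structure, which is the calibration condition.

What the generator does *not* emulate: taphonomic loss gradients,
time-averaging within sites, irregular (non-disc) ranges, niche-driven
range placement, or spatially varying detection. Passing tests therefore
demonstrate that the pipeline recovers known signals under clean sampling,
not that any particular empirical record is clean.

## Validation experiments and problem sizes

The acceptance suite runs four simulation experiments, sized to make their
statistical assertions sharp while keeping the whole suite in minutes:

* *Calibration*: 500 signal-free records (240 species, 18 sites/bin, 199
  shuffles each); the per-bin 95%-band false-positive rate must lie in
  [3%, 7%] and the mean effect size within ±0.15 of zero.
* *Power*: 100 records at full default size with ×1.5 late-bin inflation;
  the final-two-bin mean effect size must exceed +1.96 in ≥ 80% of runs.
* *Recovery*: 20 records (200 species, 30 sites/bin, uniform placement),
  effort-standardized hulls; the recovered area multiplier must fall within
  10% of the injected 1.5.
* *Pattern*: one full-size study-like record, six subset variants, 499
  shuffles; pre-Holocene bins must average below +1.96 while the final two
  bins are positive with significance stars.

Metric kernels are checked exactly (tolerance 0) against naive set-operation
oracles on 1,000 random 6 × 10 matrices, the Sørensen partition identity to
1e−12 on 10,000 random pair counts, PCA loadings against a direct
eigen-decomposition to 1e−8, and the projection's equal-area property to
0.1%.

## Known limitations

* The SEM attached to mean pairwise similarity ignores pair dependence; use
  the null model, not the SEM, for inference.
* Occupancy and the space-for-time map depend on the grid's bounding box;
  compare values only within one `grid_spec`.
* Raw (non-equalized) hull areas confound range size with site count;
  between-bin range comparisons should either equalize points or shuffle
  sites under the null model, as the pipeline does.
* The corrected Forbes index saturates at 1 for nested pairs, so it cannot
  distinguish nested from identical assemblages.
* Radiocarbon calibration is out of scope: ages are consumed as median
  calibrated years BP.
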