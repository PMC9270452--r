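# faunabeta

Quantitative tools for detecting **biotic homogenization** — the increase
over time in the average compositional similarity of ecological assemblages
(equivalently, a decline in β diversity) — in fossil and modern occurrence
records. The package grew out of the analysis of late Quaternary North
American mammal faunas, where assemblages spanning ~30,000 years BP to the
present are compared across 5,000-year time bins, but every step is generic
to any presence–absence site-by-species record with dated, georeferenced
sites. It is aimed at paleoecologists and macroecologists who need the full
chain: data vetting, similarity metrics, permutation inference, sensitivity
analysis, and the geographic and climatic covariates.

## What it computes

**Similarity.** For a pair of sites with `a` shared species, `b` unique to
the first and `c` unique to the second (`n = a + b + c`; joint absences are
excluded throughout):

- Jaccard similarity `J = a / (a + b + c)`;
- Alroy's corrected Forbes index
  `F' = a(n + √n) / (a(n + √n) + 3/2 · bc)`, which compensates for the
  richness-dependence of J;
- Baselga's partition of Sørensen dissimilarity into species turnover and
  nestedness, `β_sor = β_sim + β_sne`, in pairwise and multiple-site forms.

Per-bin homogenization is summarized as the mean of a pairwise metric over
all `s(s−1)/2` site pairs in the bin (± SEM).

**Inference.** Because similarity is sensitive to sampling intensity, trends
are tested against a site-shuffling null model: whole sites, with their
observed species complements, are reassigned randomly to time bins holding
each bin's site count fixed. Standardized effect sizes
`(observed − null mean) / null SD` with distribution-free 95% percentile
bands flag bins that are more (positive) or less (negative) homogeneous than
chance; the procedure is repeated for six standard subset variants (all
sites; east of the Rockies; south of the 49th parallel; excluding extinct
species; species > 1 kg; > 5 kg). Sensitivity designs cover radiocarbon age
error (±2,000-yr normal noise with re-binning), equal-site resampling, and
longitudinal-extent limits.

**Geography and climate.** Species range size is estimated as the summed
convex-hull area of single-linkage point clusters at the 95% level on
Behrmann equal-area projected coordinates; occupancy as the fraction of
100-km equal-area grid cells occupied (clustered sites share a cell).
Distance decay of similarity, multivariate dispersion, climate turnover
(mean pairwise distance in the first two principal components of four
climate variables per time slice), and an inverse-distance-weighted
space-for-time similarity map round out the toolkit.

**Synthetic records.** A first-class generator builds fossil-record-like
datasets with known structure — clustered sites, geodesic-disc latent
ranges, a body-mass-selective extinction pulse, per-bin range-area
inflation — so every stage of the pipeline can be validated against known
truth (null calibration, signal power, parameter recovery).

## Worked example

Generate a study-like synthetic record — seven time bins, a 72% extinction
pulse among species > 44 kg at 10,000 yr BP, and range-area inflation of
×1.5 from the early Holocene rising to ×1.875 by the modern bin — and test
for homogenization:

```r
library(faunabeta)

cfg <- generator_config(
  extinction = list(boundary = 10000, mass_kg = 44, fraction = 0.72),
  range_inflation = c(1, 1, 1, 1, 1.5, 1.5, 1.875), seed = 1)
fauna <- generate_dataset(cfg)
fauna
#> <fauna> 330 sites, 305 species, 13793 occurrences
#>   bins: 30000-25000 | 25000-20000 | 20000-15000 | 15000-10000 | 10000-5000 | 5000-500 | modern

bundle <- run_pipeline(fauna = fauna, subsets = c("all", "mass_gt_1"),
                       reps = 999, seed = 1)
report(bundle)
#> all:
#>          bin observed effect_size sig
#>  30000-25000   0.1565        0.13
#>  25000-20000   0.1144       -2.63   *
#>  20000-15000   0.1563        0.04
#>  15000-10000   0.1580        0.33
#>   10000-5000   0.1677        1.80
#>     5000-500   0.1747        3.72   *
#>       modern   0.1794        3.88   *
#>
#> mass_gt_1:
#>          bin observed effect_size sig
#>  30000-25000   0.1626        0.21
#>  25000-20000   0.1164       -2.41   *
#>  20000-15000   0.1613       -0.02
#>  15000-10000   0.1680        0.74
#>   10000-5000   0.1862        3.14   *
#>     5000-500   0.1815        3.38   *
#>       modern   0.1992        5.21   *
```

Each row gives the observed mean pairwise Jaccard similarity in the bin, its
standardized effect size against 999 site-shuffles, and a star where the
observation falls outside the null's 95% band. The injected Holocene signal
is recovered: pre-Holocene bins sit at or below null expectations while the
final bins are strongly, significantly homogenized — and the > 1 kg subset
homogenizes earlier and harder, as its ranges inflate while small-range
endemics drop out.

The numbered scripts under `analysis/` walk the full study: `01_simulate.R`
(build the record and climate grid), `02_similarity.R` (metrics and the
similarity-vs-richness control), `03_null_models.R` (null model, effect
sizes, age-error and resampling sensitivity), `04_ranges_occupancy.R`,
`05_climate.R`, and `06_space_for_time.R`. Each writes tidy CSVs under
`results/`.

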