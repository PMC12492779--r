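# resurveydiv

Tools for quantifying a century of change in species-rich grasslands from
paired vegetation surveys: a historical baseline of tiny (0.09 m²) plots
recorded as per-species dry biomass, and a modern resurvey of the same
locations recorded as visually estimated percent cover. Because historical
plots cannot be relocated exactly, each one is represented by a *potential
area* containing several randomly placed modern plots; all inference is
built around that hierarchical, imprecisely paired design.

The package is aimed at vegetation ecologists running resurvey studies: it
covers the full path from raw abundance tables to survey contrasts and
their elevation dependence, and ships a synthetic-data generator that
emulates the whole design with known ground truth, so every stage can be
validated without any external data.

## What it computes

**Diversity.** All three facets use Rao's quadratic entropy
Q = Σᵢ Σⱼ pᵢ pⱼ dᵢⱼ, the expected dissimilarity between two randomly drawn
individuals, with facet-specific species distances dᵢⱼ:

- *taxonomic*: identity distances (dᵢⱼ = 1 for i ≠ j), under which Q is the
  Gini–Simpson index and richness is reported alongside, with a +0.9
  detection correction for resurvey plots (visual cover estimation
  overlooks on average 0.9 species per plot relative to lab biomass
  sorting);
- *functional*: Gower distances on the leaf–height–seed traits (specific
  leaf area, plant height, seed mass; the latter two log₁₀-transformed),
  range-normalized over the analysis pool;
- *phylogenetic*: cophenetic (patristic) distances from a Newick tree.

α/β/γ decomposition follows the Jost equivalent-number correction
1/(1−Q): for a plot pair, β_add = γ_eq − ᾱ_eq with γ from the pooled
community, and band-level γ is the union richness of one seeded random
plot per potential area and survey.

**Community characteristics.** Community-weighted means of the seven
ecological indicator values (temperature, light, moisture, reaction,
nutrients, mowing tolerance, hemeroby; 1–5 ordinal scale), Grime CSR
strategy composition (3-letter codes decomposed onto the simplex, e.g.
`ssr` → c = 0, s = 2/3, r = 1/3), and cover shares of Poaceae,
Cyperaceae + Juncaceae, and forbs.

**Inference.** Survey contrasts from linear mixed models
(`value ~ survey + (1|area) + (1|area:survey)`, Satterthwaite p-values),
per-area Δ (resurvey mean − historical mean) regressed on elevation with
zero-crossing elevations, 11 elevational bands (remainder areas absorbed
by the lowest bands: 277 areas → 26, 26, 25×9) with band-level β and γ
contrasts, and a pseudo-turnover check comparing between-survey
Bray–Curtis dissimilarity with the within-resurvey (relocation) baseline.

## Worked example

```r
library(resurveydiv)

cfg <- scenario_config(n_areas = 40, seed = 1)   # defaults: 38% loss at
ds  <- generate_dataset(cfg)                     # 500 m, 11% at 2000 m
ds
#> Synthetic resurvey dataset
#>   areas:      40 (322-2497 m)
#>   plots:      212 (61 historical, 151 resurvey)
#>   pool size:  300
#>   seed:       1

res <- run_pipeline(cfg, do_bands = FALSE)
res$survey_effects$richness
#> Survey effect [richness]: -4.086 (se 0.429, df 39.5, p 8.52e-12)
#>   historical 18.31 -> resurvey 14.23 (-22.3%)

res$delta_fits[res$delta_fits$metric == "richness", ]
#>     metric intercept   slope r2_adj  p_slope  n crossing_elevation_m
#> 1 richness     -8.59 0.00317  0.566 1.32e-08 40                 2707
```

Richness is about 22% lower in the resurvey, and the per-area Δrichness
increases by ~0.003 species per metre of elevation (losses shrink with
elevation), with the fitted line crossing zero only above the gradient.
The same result object carries the effects for all other metrics — e.g.
the nutrient-indicator CWM rises by 0.56 units (+19%) and the Poaceae
cover share by 5.4 percentage points — plus the pseudo-turnover contrast:

```r
res$pseudo_turnover$effect$estimate
#> [1] 0.127   # between-survey BC exceeds within-resurvey BC
```

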