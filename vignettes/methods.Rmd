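---
title: "Methods: ensemble distribution models and biodiversity change in Arctic seas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble distribution models and biodiversity change in Arctic seas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Arctic marine communities are redistributing under warming and sea-ice
loss. Detecting that signal from presence-only archive records requires a
chain of methods: habitat models fit per species from occurrences and
gridded summer covariates, richness and compositional-change maps built
from the modelled ranges, pairwise co-occurrence screens for shifts in
potential species associations, and trend maps of the climate and
productivity fields themselves. `arcbiodiv` implements that chain as a
seeded, configured pipeline, and pairs it with a virtual-species generator
so every stage can be tested against known truth without any data
downloads.

## Stages and their models

### Synthetic world

`make_grid()` builds a regular lon-lat grid (cell-center registration,
WGS84 degrees) whose marine domain is split into longitude-sector regions —
stand-ins for the eight circumpolar monitoring-programme marine areas — with
a southern land fringe for coastline-dependent covariates. All distances in
the package are great-circle (haversine, Earth radius 6371 km); this keeps
km-denominated rules like the 100-km buffer exact without projection
machinery.

`simulate_environment()` emits annual summer layers for sea surface
temperature (SSST, °C), sea ice concentration (SSIC, %), chlorophyll-a
(SCHL, mg·m⁻³), zooplankton biomass (SZOOC, g·m⁻²) and salinity (PSU), plus
static depth and distance-to-coast, as
`baseline(lat) + trend·(year − year₀) + interannual anomaly + pixel noise`,
clipped to physical ranges. Defaults impose +0.3 °C/decade warming and
−8 %/decade ice loss with productivity increases of +0.4 units/decade —
magnitudes chosen to sit inside the decadal "large change" windows the
hotspot stage screens for, so the synthetic world actually contains the
phenomenon the detector targets. Distance to the summer ice edge is
recomputed every year as the shortest great-circle distance to the 15 %
sea-ice-concentration contour (taken as the icy cells bordering non-icy
cells, which therefore get distance exactly 0). Degenerate years follow a
fixed rule — all-ice: 0 everywhere; ice-free: distance to the northern
domain edge — preserving a total ordering with no undefined cells.

Virtual species (`define_virtual_species()`) carry product-of-Gaussians
suitability on selected covariates. Truth occupancy thresholds suitability
at the quantile achieving a prevalence target (standard virtual-ecologist
practice: the true range is then known exactly), and the poleward range
front may advance at most `mobility_km_per_year` from its first-year
position. Guild defaults encode the familiar apex/mesopredator contrast of
Arctic marine communities: apex species are wide-ranging (all regions, thermal
breadth 2.5–3.5 °C, 150 km/yr) and mesopredators more sedentary (3–6
contiguous regions, 1.2–2 °C, 50 km/yr); the default desk community is 12
species (4 apex, 8 meso) on a 40×360 one-degree grid over 20 years — the
2000–2019, 8-region design at desk scale. `sample_occurrences()` draws
presence-only records with probability ∝ suitability × occupancy × effort
bias (default bias decays with distance to coast, e-folding 300 km,
mimicking coastal survey effort) and jitters them within cells.

### Occurrence preparation

`clean_occurrences()` keeps at-sea, in-bounds records and removes exact
coordinate duplicates per species-year. `thin_occurrences()` enforces a
minimum nearest-neighbour distance (default 100 km) by iteratively deleting
the record with the most close neighbours (ties uniform at random), with 10
randomized repetitions keeping the largest retained set — the behaviour
contract of the published thinning algorithm without copying its code.

Pseudo-absences are drawn in the published two-round scheme. Round one:
random ocean cell centers outside a 100-km buffer around that year's
presences, used only to rank covariates. Round two: additionally outside
the species' occupied covariate ranges (the environmental profile built
from pooled presences). A cell is eligible when **at least one** profiled
variable lies outside its occupied range — the complement of the joint
occupied hyper-rectangle, the least restrictive faithful reading of
"pixels within the occupied ranges are excluded"; an `all_outside` variant
is config-exposed. Pseudo-absence positions are cell centers sampled
without replacement (covariates are cell-resolved, so sub-cell placement
adds no information). The buffer is applied per-year, matching the
annually-compiled presence sets; the study-scale target of 10 000
points/year is exposed in config with a desk-scale default of 500/year.

### Ensemble distribution models

Five classifier families span the parametric/nonparametric range of the
large SDM platforms: ridge-regularized logistic regression (`glmnet`,
fixed mild penalty — no tuning by design), a spline classifier
(`mgcv`), a bagged random-decision-forest, gradient-boosted depth-2 trees,
and k-nearest-neighbours. The tree and kNN learners are implemented in the
package (the deployment environment ships no tree/kNN package): CART-style
regression trees with 32-bin histogram splits (SSE criterion, which equals
the gini criterion on 0/1 labels up to a constant), bagging with 0.632
subsampling and √p feature sampling, logistic-loss gradient boosting with
shrinkage 0.1, and kNN (k = 10) on z-scored features over at most 1 500
seeded prototypes. These sizes are runtime choices for a single-CPU desk
budget, not tuned quantities.

Variable selection follows the averaged-importance rule: importance of a
variable is `1 − cor(predictions, predictions after permuting it)`,
averaged over permutations and algorithms, clipped to [0, 1] (undefined
correlations from constant predictions count as importance 0); variables
above the across-variable mean are kept, with the first argmax retained if
all tie so the selection is never empty. The correlation is computed on a
seeded subsample of at most 1 000 rows — it is a rank statistic and
stabilizes far below study-scale row counts.

Evaluation sweeps 101 thresholds in [0, 1], reports TSS and kappa at the
TSS-maximizing threshold (smallest on ties — deterministic) plus
threshold-free AUC, averaged over stratified 80/20 split repetitions
(function default 3; the desk config uses 2 to stay inside the single-CPU
budget). The committee-mean ensemble averages the **binary** maps of
members whose TSS passes the gate (default 0.7, the conventional
"good model" cut in the SDM literature; config-exposed), giving scores on
the lattice 0, 1/m, …, 1; the ensemble map is
score ≥ 0.5, then zeroed outside the species' allowed regions (the expert
range constraint). A species with no admissible member is an error at the
operation level and an excluded, logged species at the pipeline level.

### Biodiversity metrics

Richness is the per-pixel count of present species. Richness trends use
per-pixel ordinary least squares on year (published pan-Arctic analyses reserve
Mann–Kendall for climate variables and report linear richness trends);
decade scaling is slope × 10, and areas of species accrual are pixels at
or above 1 species/decade (boundary included). The accrual series — annual
regional mean richness over accrual cells — is emitted with ice-regime
flags and temperature anomalies (the Hovmöller data table) plus the Pearson
correlation between the two series.

Compositional change between two regime maps uses the Sorensen
dissimilarity partition: with `a` shared, `b` only-A, `c` only-B species,
`β_sor = (b+c)/(2a+b+c)`, turnover `β_sim = min(b,c)/(a+min(b,c))`,
nestedness `β_sne = β_sor − β_sim`. Pixels empty in both communities are
flagged missing and excluded from summaries. Regime maps average annual
binaries over the pooled low- or high-ice years and re-binarize at ≥ 0.5.
Range-size change is the four-way loss/gain/stable-present/stable-absent
partition with percentages relative to baseline-present cells and direction
`sign(gain − loss)`.

### Co-occurrence

The probabilistic pair test is implemented from first principles: with two
species occupying `N1` and `N2` of `N` sites independently, the co-occupied
count is hypergeometric,
`P(Q=j) = C(N1,j)·C(N−N1,N2−j)/C(N,N2)` on the feasible range; `p_gt` and
`p_lt` are the tail sums including the observed value, evaluated in
log-gamma space and clipped to [0, 1]. Classification uses strict
`p < α` (α = 0.05, no multiple-testing correction, matching the cited
convention); pairs with expected co-occurrence below 1 are flagged
unanalyzable and logged rather than silently dropped; all-zero species
columns are excluded from enumeration. Annual class counts per region are
trend-fit (OLS slope, adjusted R² = 1 − (1−R²)(n−1)/(n−2)) and correlated
with regional richness; zero-variance series report slope 0 and a missing
correlation.

### Climate

Regional summer anomalies subtract a climatology mean — the scenario's
truth baseline field at desk scale, standing in for a long pre-record
average that predates the generated record; a first-k-years alternative is
config-exposed. A year is low-ice when its regional ice anomaly is
negative; pooled regimes are the intersection of common classifications
across regions, degrading to per-region analyses with a warning when empty.
Temperature anomalies ≥ 0.5 °C carry a moderate/high-warming flag.

Pixel-wise Mann–Kendall trends use the exact S statistic, tie-corrected
variance `[n(n−1)(2n+5) − Σ t(t−1)(2t+5)]/18`, ±1 continuity-corrected
normal z (0 when S = 0) and the Sen slope (median pairwise slope). A
"large change" is a significant trend (p < 0.05) of the required sign whose
decadal Sen slope falls inside a per-variable magnitude window — defaults
follow realized ranges reported for recent pan-Arctic summers (SSST +0.21…+0.76 °C,
SSIC −76…−2 %, SCHL +0.26…+0.73 mg·m⁻³, SZOOC +0.21…+0.75 g·m⁻²) since the
underlying selection rule is not published; the windows are config, not
logic. A hotspot is a pixel with ≥ 2 of 4 large changes; per-region
percentages of accrual cells overlapping the hotspot and single-variable
masks are reported.

## What the synthetic world does and does not establish

The generator reproduces the *structure* of real pan-Arctic inputs: a multi-year
warming/ice-loss environment with regional structure, guild-specific niches
with poleward shift capacity, and spatially biased presence-only sampling
with known truth occupancy. It does not emulate ocean dynamics, daily
resolution, observation-platform heterogeneity, taxonomic error, or the
real 18-covariate collinearity structure. A green test therefore
establishes that the *methods* are implemented correctly and can recover
imposed signals at desk scale — not that the published effect sizes would
be reproduced from the real downloads, which is why acceptance is
property- and oracle-based rather than a comparison against published
regional effect sizes.

## Numerical choices and degenerate inputs

* Seeding: one master seed; every stochastic operation derives a named
  sub-seed (`sub_seed()`), so reruns are bit-identical and stage reordering
  cannot perturb other stages.
* Threshold ties: smallest TSS-maximizing threshold; committee boundary
  0.5 counts as presence; accrual boundary 1/decade included.
* Ice-edge degeneracies and empty pooled regimes degrade as described
  above rather than erroring.
* Empty eligible pseudo-absence pools, single-class training or test sets,
  empty niche specifications, and out-of-bounds co-occurrence counts are
  explicit errors.
* Raster I/O is long-format CSV (`variable,year,lat,lon,value`): the
  deployment environment has no NetCDF/GeoTIFF R library, so the CF-style
  dimension contract is kept in a plain-text container.

## Known limitations

Thinning is O(n²) per species-year group; the regional trend table assumes
complete year coverage (complete-case pixels only); the co-occurrence stage
tests annual binary maps per year (whether published applications use
multi-year windows is not stated); and the five-member roster is a
desk-scale stand-in for the ten-algorithm platform ensemble, config-
extensible but not a reproduction of any specific platform's internals.
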