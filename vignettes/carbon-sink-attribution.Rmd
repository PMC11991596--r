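---
title: "Estimating and attributing a regional vegetation carbon sink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and attributing a regional vegetation carbon sink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nepsink)
```

## The problem

Net ecosystem productivity (NEP) — net primary productivity (NPP) minus
soil heterotrophic respiration (Rh) — measures whether vegetated land takes
up carbon (NEP > 0, a sink) or releases it (NEP < 0, a source). For a
subtropical, rapidly urbanizing province observed on a 1-km grid, the
questions this package answers are: how large is the sink, how is it
trending, which climate variables control its interannual variation, and
which natural and anthropogenic surfaces explain its spatial pattern.

`nepsink` implements that chain end to end on gridded inputs and ships a
synthetic-scenario generator with recorded ground truth, so every stage is
testable without multi-gigabyte remote-sensing downloads.

## Productivity model

NPP follows the light-use-efficiency (CASA family) decomposition

$$\mathrm{NPP}(x,t) = \mathrm{APAR}(x,t) \times \varepsilon(x,t),$$

per pixel $x$ and month $t$, with annual NPP the exact sum of the twelve
monthly values. The sub-models are the canonical CASA forms, with every
constant in a configuration table (`casa_params()`), not in code:

* **FPAR** rises linearly with NDVI between a per-vegetation-type bare-soil
  minimum (`ndvi_min`, FPAR = 0) and saturation maximum (`ndvi_max`),
  capped at `fpar_max` = 0.95.
* **APAR** = SOL × FPAR × 0.5, where SOL is monthly incoming solar
  radiation (MJ m⁻²) and 0.5 the photosynthetically active fraction.
* **Temperature stresses.** $T_1 = 0.8 + 0.02\,T_{opt} - 0.0005\,T_{opt}^2$
  (quadratic in the optimum-month temperature, zero below −10 °C) and the
  asymmetric logistic penalty
  $T_2 = 1.1814 / \big[(1 + e^{0.2(T_{opt} - 10 - T)})(1 + e^{0.3(T - T_{opt} - 10)})\big]$.
  $T_{opt}$ is the climatological temperature of the month with maximal
  NDVI at each pixel. Note that even at $T = T_{opt}$ the product
  $T_1 T_2$ is slightly below 1 (≈ 0.99) — the classic parameterization,
  which the tests assert as a band rather than forcing exact unity.
* **Water stress.** $W = 0.5 + 0.5 \min(1, R/\mathrm{PET})$, a monthly
  supply/demand ratio floored at 0.5. Demand is Thornthwaite monthly PET
  (temperature-only), chosen because the synthetic climate carries no
  humidity or soil information; where PET is zero (freezing months) the
  ratio is taken as 1, i.e. no water limitation is asserted without
  evaporative demand.
* **εmax** is a per-type maximal light-use efficiency (g C MJ⁻¹); defaults
  0.985 (broadleaf forest) and 0.542 (shrub/grassland, cropland) follow
  widely used CASA calibrations.

These sub-model choices are this package's own: the upstream literature the
chain descends from prints only the product equation and cites refinements
that are not reproducible from text. The product identity
NPP = APAR × ε, the [0, εmax] bounds, monotonicity in NDVI and linearity in
SOL are enforced by tests.

## Respiration and the carbon balance

Monthly soil heterotrophic respiration uses the empirical equation

$$R_h = 0.22\,\big(e^{0.0913\,T} + \ln(0.3145\,R) + 1\big) \times 30 \times 46.5\%$$

(g C m⁻² month⁻¹; T in °C, R in mm). Decisions worth stating:

* The equation is applied **monthly** (its ×30 day factor and monthly
  time index), then summed to annual; the alternative annual application is
  isolated behind `compute_rh()` should a user want to change it.
* The printed constants are used literally: 46.5 % as exactly 0.465, the
  day factor as exactly 30 for every month.
* Cells with R ≤ 0 in a month (logarithm undefined) are **masked** for
  that month and counted in a diagnostics attribute, never silently zeroed
  or clamped. The generator keeps monthly precipitation positive (see
  below), so under default conditions no cells are lost.

NEP = NPP − Rh per pixel and month. Pixels are classed sink (NEP > 0),
source (NEP < 0) or neutral (exactly 0 — the rule's strict inequalities
leave zero undefined, and neutral keeps the classification total).
Regional totals multiply by the pixel area from the georeference (assumed
equal-area; 1-km pixels → 10⁶ m²) and are reported in Tg C a⁻¹.

## Trend analysis

Per-pixel trends use the closed-form least-squares slope against the time
index $i = 1..n$ and the regression F-test
$F = r^2(n-2)/(1-r^2)$ on $(1, n-2)$ degrees of freedom, giving five
classes: extremely significant increase ($p < 0.01$, slope > 0),
significant increase ($0.01 \le p < 0.05$), stable ($p \ge 0.05$), and the
two decrease classes symmetrically. Conventions: boundary p-values
(exactly 0.01 or 0.05) fall to the less-significant class; a constant
series gets slope 0 with $p = 1$ so maps stay total; series shorter than 3
are masked. The closed form is tested against `lm()` to 10⁻¹⁰, and the
F-test's type-I error and null p-value uniformity are verified by
simulation.

## Climate attribution

For each pixel, annual NEP is related to annual climate series — mean
temperature, total precipitation, total solar radiation (annual, to match
the trend convention; the monthly alternative would mix the seasonal cycle
into what is meant as an interannual question):

* **Second-order partial correlations** of NEP with each factor,
  controlling the other two, from the inverse of the 4-variable correlation
  matrix; significance by t-test with $n - 4$ degrees of freedom.
* **Multiple correlation** of NEP on all three factors (OLS with
  intercept); significance by F-test on $(3, n-4)$ degrees of freedom.
* **Nine driving types.** The typology gate is the multiple correlation:
  $p_R \ge 0.05$ → *non-climatic*. Within the gate, the set of
  individually significant partials ($p < 0.05$) decides: exactly one →
  that factor's type (3 types); exactly two → the pairwise type (3 types);
  all three → *strongly driven by T, P, S*; none → *weakly driven by
  T, P, S*. This decision table is a **reconstruction**: the type names in
  circulation imply exactly this partition, but the cutoffs (e.g. whether
  "strongly" should key on 0.01 instead of 0.05) are not fixed by any
  single authority. The nine labels partition every valid pixel; pixels
  with masked years or degenerate series are dropped (complete-case) and
  counted.

Both correlation routines are cross-checked against independent
formulations (residualization; `lm()` R²) to 10⁻¹⁰.

## Optimal-parameter GeoDetector

The spatial attribution uses the GeoDetector q-statistic

$$q = 1 - \frac{\sum_{h=1}^{L} N_h \sigma_h^2}{N \sigma^2},$$

the share of response variance explained by a stratification
(population variances, N-weighted, exactly as written). Components:

* **Discretization.** Continuous factors are cut by five schemes (equal
  width, quantile, natural breaks, geometric, standard deviation) at
  L = 3..10; the (scheme, L) pair maximizing q is kept, with candidates
  whose smallest stratum holds < 2 samples discarded, and ties resolved to
  the smaller L then the earlier scheme. Natural breaks are computed by
  deterministic 1-D k-means seeded at quantile centers (the standard fast
  Jenks approximation; exact Fisher–Jenks would be O(L·n²) for no material
  gain at these sample sizes).
* **Significance** uses the noncentral-F transform of q from the
  GeoDetector literature; a seeded permutation test is provided as a
  distribution-free cross-check, and the two concur in tests.
* **Interaction detector.** q of the cross-classification against the
  singles: nonlinear enhancement ($q_{12} > q_1 + q_2$), linear/bivariate
  enhancement ($\max < q_{12} \le q_1+q_2$), independence (additive within
  10⁻⁶), linear/univariate weakening, nonlinear weakening. A structural
  fact the tests assert: on complete samples the cross-classification
  refines both factors, so $q_{12} \ge \max(q_1, q_2)$ **always** — the
  weakening types can only arise when small cross-strata are merged
  (the detector merges strata under the minimum size into the stratum with
  the nearest response mean, logging the count).
* **Risk detector.** Per-stratum mean response, the optimal (maximum-mean)
  stratum with its value range, and Welch t-tests between all stratum
  pairs.

The 12-factor design mirrors common practice: annual mean temperature,
annual precipitation, annual solar radiation, annual mean NDVI, elevation,
slope, population density and nighttime light as continuous factors
(optimally discretized), and impervious-surface change, human-footprint
change, land-use change and arable-expansion change consumed as native
categorical layers with 3, 6, 12 and 4 classes.

## The synthetic scenario

`nep_scenario()` defines the desk-scale study conditions: 100 × 100 pixels
of 1 km over 24 years (2000–2023), a subtropical-monsoon parameterization
(annual mean temperature 16 °C with ±10 °C seasonal amplitude; annual
precipitation ≈ 1440 mm peaking in June; radiation ≈ 380 MJ m⁻² month⁻¹
mean), a southwest-high terrain that carries the spatial gradients, NDVI
coupled to standardized temperature and precipitation anomalies and clipped
to [−0.2, 1], and a default warming trend of 0.02 °C a⁻¹. Precipitation
noise is proportional to the seasonal level (constant coefficient of
variation), which is both closer to real monthly precipitation records
than additive noise and keeps monthly totals strictly positive, so the
respiration equation's log never sees zero under default conditions.

Every layer draws from an independent substream of the master seed:
identical scenario + seed reproduces bit-identical stacks, and adding a
layer never perturbs existing ones. Injected truths — trend slopes,
per-stratum driver effects, prescribed partial correlations — are recorded
in truth records that the tests read back, never re-derived.

What the generator does **not** emulate: sensor artifacts, cloud gaps and
compositing; spatial autocorrelation of the noise fields (pixels are
independent given the smooth mean surfaces); land-cover change over time;
lagged or nonlinear climate responses. Passing tests therefore demonstrate
correctness of the estimators under known ground truth, not calibration
against any real region.

## Numerical conventions and problem sizes

Grids are cell-center registered, row 1 = north; rasters travel as
Arc/Info ASCII grids (a standard text format with an explicit nodata
value) plus a JSON sidecar for CRS and units, and temporal stacks as
per-band files with a manifest. Bilinear resampling is used for continuous
layers and nearest-neighbour for categorical codes (bilinear over category
codes would invent classes); nodata is never interpolated into valid
cells. An equal-area CRS is assumed for area totals.

Default experiment sizes — the full pipeline at 100 × 100 × 24 years
(seconds on one core), trend simulations at 1000–2000 pixels, driver
recovery at 30 × 30 × 100 replicates, correlation recovery at n = 500 ×
100 replicates — were chosen so the complete suite exercises every stage
at statistically meaningful sample sizes while staying desk-scale.

## Known limitations

* The CASA constants ship as defaults, not calibrations; absolute NPP/NEP
  levels from the synthetic scenario are illustrative.
* The q-statistic significance ignores spatial autocorrelation, which
  inflates effective sample size on real rasters (as it does in standard
  GeoDetector practice); the permutation fallback shares the limitation.
* The nine-type climate typology is a reconstruction (above) and should be
  read as one defensible partition, not the only one.
* North-up, axis-aligned georeferences only; reprojection is out of scope.
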