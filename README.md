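# nepsink

Estimation and driver attribution of a regional vegetation carbon sink
from gridded monthly data.

Terrestrial vegetation takes up carbon through photosynthesis and soils
release it through microbial decomposition; the balance per pixel and year
is net ecosystem productivity,

    NEP(x, t) = NPP(x, t) − Rh(x, t),

with NEP > 0 marking a carbon sink and NEP < 0 a source. `nepsink` is an
analysis workflow for ecologists and carbon-cycle modellers who want that
balance, its trend, and its drivers on a raster grid:

1. **NPP** by a light-use-efficiency (CASA-style) model,
   `NPP = APAR × ε`, where APAR is absorbed photosynthetically active
   radiation (SOL × FPAR × 0.5, FPAR linear in NDVI per vegetation type)
   and ε is the maximal efficiency εmax down-weighted by temperature and
   water stress scalars.
2. **Rh** by the empirical equation
   `Rh = 0.22 (e^{0.0913 T} + ln(0.3145 R) + 1) × 30 × 46.5 %`
   (monthly; T in °C, R in mm), then **NEP**, sink/source classification
   and regional totals in Tg C a⁻¹.
3. **Trends**: per-pixel closed-form least-squares slope of annual NEP
   with an F-test and five significance classes.
4. **Climate attribution**: per-pixel second-order partial correlations of
   NEP with temperature, precipitation and solar radiation, the multiple
   correlation, and a nine-class climate-driving typology.
5. **Optimal-parameter GeoDetector**: factor detection by the q-statistic
   `q = 1 − Σ N_h σ_h² / (N σ²)` with discretization optimized over five
   break schemes × stratum counts, pairwise interaction typing, and risk
   detection of each factor's optimal range.

Because the real inputs of such studies are large proprietary-resolution
stacks, the package ships a **synthetic-scenario generator** with recorded
ground truth (injected trends, stratified driver effects, prescribed
partial correlations) that emulates a subtropical monsoon province on a
1-km grid; every stage is exercised and validated against that truth.
Rasters travel as Arc/Info ASCII grids (text, nodata-aware) with JSON
sidecars — no binary formats required.

## Worked example

```r
library(nepsink)

scenario <- nep_scenario(shape = c(60L, 60L), years = 2000:2023, seed = 1L)
climate  <- generate_climate(scenario)
veg      <- generate_vegetation(scenario, climate)

npp <- compute_npp(climate, veg$ndvi, veg$vegtype)
nep <- compute_nep(npp, compute_rh(climate$T, climate$R))

budget <- aggregate_regional(apply(nep$nep_annual, c(1, 2), mean),
                             nep$transform)
print(budget)
#> regional budget: sink 1.2563 Tg C a-1, source 0.0000 Tg C a-1, net 1.2563
#>   sink area 100.00%, mean NEP 349.07 g C m-2 a-1 (n = 3599)

tm <- trend_map(nep$nep_annual)
cat(sprintf("mean NEP trend: %.3f g C m-2 a-1 per year; %.1f%% significantly increasing\n",
            mean(tm$slope, na.rm = TRUE),
            100 * sum(tm$class_proportions[c("extremely_significant_increase",
                                             "significant_increase")])))
#> mean NEP trend: 0.422 g C m-2 a-1 per year; 7.8% significantly increasing
```

Reading: over this 60 × 60 km synthetic region the multi-year mean NEP is
349 g C m⁻² a⁻¹, every pixel is a sink, the regional uptake is 1.26 Tg C
per year, and the sink strengthens by ~0.42 g C m⁻² a⁻¹ each year (driven
by the scenario's configured 0.02 °C a⁻¹ warming through the productivity
model), with 7.8 % of the area crossing the p < 0.05 significance bar.

## The analysis workflow

The numbered scripts under `analysis/` run the study end to end on the
default 100 × 100 × 24-year scenario and write small tables under
`results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | builds the synthetic region (climate, NDVI, vegetation, 12 driver layers) |
| `02_npp_nep.R` | NPP + validation, Rh, NEP, annual regional budgets |
| `03_trend.R` | per-pixel trend map and five-class proportions |
| `04_attribution.R` | partial/multiple correlations and the nine driving types |
| `05_opgd.R` | optimal-parameter GeoDetector q ranking, interactions, risk optima |

`run_pipeline()` performs the same sequence in one call from a
configuration list or YAML file, writes a machine-readable report, and is
byte-identical across reruns with the same seed.

## Further reading

The methods vignette (`vignettes/carbon-sink-attribution.Rmd`) documents
the model equations and their assumptions, every tunable parameter with
units and defaults, what the synthetic generator does and does not
emulate, numerical conventions, and known limitations.
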