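#' Synthetic study scenario
#'
#' Defines a reproducible desk-scale study region with known ground truth:
#' monthly climate with seasonal cycles, spatial (terrain-driven) gradients,
#' interannual noise and optional linear trends; NDVI coupled to climate;
#' a vegetation-type map; and stratified driver layers with known additive
#' effects on NEP. The defaults emulate a subtropical monsoon province on a
#' 1-km grid: 100 x 100 pixels over 2000-2023 (24 years), mean annual
#' temperature around 16 degC, annual precipitation 1000-2000 mm, and a
#' southwest-high / northeast-low terrain gradient.
#'
#' Each generator draws from an independent substream of `seed`, so adding a
#' layer never perturbs previously generated ones, and an identical scenario
#' + seed reproduces bit-identical output.
#'
#' @param shape `c(nrow, ncol)` of the grid.
#' @param years integer vector of consecutive years.
#' @param seed master integer seed.
#' @param dx pixel size in metres (default 1000 m, i.e. 1 km).
#' @param climate_params per-variable list (`T`, `R`, `SOL`) with elements
#'   `mean` (annual mean level), `amp` (seasonal sinusoid amplitude),
#'   `grad` (signed range added across the terrain gradient), `sd`
#'   (interannual Gaussian noise sd per pixel-month) and `trend` (additive
#'   linear trend per year). Units: degC for `T`, mm per month for `R`,
#'   MJ m-2 per month for `SOL`.
#' @param ndvi_params list with `baseline` (mean NDVI level), `relief` (NDVI
#'   increase across the terrain gradient), coupling coefficients `a` (to
#'   standardized temperature) and `b` (to standardized precipitation), and
#'   noise `sd`. NDVI is clipped to `[-0.2, 1]`.
#' @param driver_params named list of driver definitions; each is
#'   `list(type = "categorical", L = <strata>, effects = <numeric L>)` or
#'   `list(type = "continuous", beta = <effect per unit>)`. The defaults
#'   mirror a 12-factor design: four generated continuous surfaces
#'   (elevation, slope, nighttime light, population density) and four
#'   categorical change layers with 3/6/12/4 classes (impervious-surface,
#'   human-footprint, land-use, arable-expansion change).
#' @param response_params list with `baseline` mean NEP-like response
#'   (g C m-2 a-1) and Gaussian `noise_sd` for the synthetic driver-response
#'   surface.
#' @return object of class `nep_scenario`.
#' @export
nep_scenario <- function(shape = c(100, 100), years = 2000:2023, seed = 42L,
                         dx = 1000,
                         climate_params = list(
                           T = list(mean = 16, amp = 10, grad = -4,
                                    sd = 0.8, trend = 0.02),
                           R = list(mean = 120, amp = 80, grad = 40,
                                    sd = 25, trend = 0),
                           SOL = list(mean = 380, amp = 180, grad = -30,
                                      sd = 20, trend = 0)),
                         ndvi_params = list(baseline = 0.55, relief = 0.25,
                                            a = 0.06, b = 0.04, sd = 0.04),
                         driver_params = default_driver_params(),
                         response_params = list(baseline = 380,
                                                noise_sd = 30)) {
  stopifnot(length(shape) == 2, all(shape >= 2))
  if (length(years) < 1) stop("zero-length year range")
  structure(list(shape = as.integer(shape), years = as.integer(years),
                 seed = as.integer(seed), dx = dx,
                 climate_params = climate_params, ndvi_params = ndvi_params,
                 driver_params = driver_params,
                 response_params = response_params),
            class = "nep_scenario")
}

#' Default driver design of the synthetic scenario
#'
#' Four continuous surfaces and four categorical change layers whose class
#' counts (3, 6, 12, 4) follow the standard products they emulate. `effects`
#' are additive contributions to the synthetic NEP response in g C m-2 a-1;
#' `beta` is the effect per unit of the (0-1 rescaled) continuous surface.
#' @export
default_driver_params <- function() {
  list(
    elevation = list(type = "continuous", beta = 120),
    slope = list(type = "continuous", beta = 60),
    nighttime_light = list(type = "continuous", beta = -90),
    population_density = list(type = "continuous", beta = -60),
    impervious_change = list(type = "categorical", L = 3L,
                             effects = c(40, -40, -120)),
    human_footprint_change = list(type = "categorical", L = 6L,
                                  effects = c(90, 55, 20, -15, -50, -85)),
    land_use_change = list(type = "categorical", L = 12L,
                           effects = seq(80, -80, length.out = 12)),
    arable_expansion_change = list(type = "categorical", L = 4L,
                                   effects = c(30, 0, -30, -60)))
}

# Independent substreams of the master seed (kept < 2^31).
sub_seed <- function(scenario, stream) {
  (scenario$seed %% 100000L) * 10000L + stream
}

scenario_month_index <- function(scenario) {
  data.frame(year = rep(scenario$years, each = 12L),
             month = rep(1:12, times = length(scenario$years)))
}

# Deterministic smooth random field in [0, 1] (separable moving-average
# smoothing of white noise, rescaled).
smooth_field <- function(nr, nc, scale = 7L) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  k <- rep(1, scale) / scale
  pad <- function(m, n) m[c(rep(1, n), seq_len(nrow(m)), rep(nrow(m), n)), ]
  for (pass in 1:2) {
    z <- apply(pad(z, scale), 2, function(col)
      stats::filter(col, k, sides = 2)[(scale + 1):(scale + nr)])
    z <- t(apply(pad(t(z), scale), 2, function(col)
      stats::filter(col, k, sides = 2)[(scale + 1):(scale + nc)]))
  }
  (z - min(z)) / (max(z) - min(z))
}

#' Terrain of a scenario
#'
#' Deterministic (seed-substream) elevation surface, high in the southwest
#' and low toward the northeast coast, plus its slope (finite-difference
#' gradient magnitude in degrees) and the normalized relief field used as
#' the spatial-gradient carrier for climate and NDVI.
#'
#' @param scenario a [nep_scenario()].
#' @return list of `raster_grid`s `elevation` (m), `slope` (deg) and the
#'   unitless `relief` in `[0, 1]`.
#' @export
scenario_terrain <- function(scenario) {
  nr <- scenario$shape[1]; nc <- scenario$shape[2]
  withr::with_seed(sub_seed(scenario, 1L), {
    ri <- (seq_len(nr) - 0.5) / nr   # 0 north -> 1 south
    ci <- (seq_len(nc) - 0.5) / nc   # 0 west  -> 1 east
    bump <- outer(ri, ci, function(r, c)
      exp(-((r - 0.75)^2 + (c - 0.25)^2) / 0.18))
    relief <- 0.75 * bump + 0.25 * smooth_field(nr, nc, 9L)
    relief <- (relief - min(relief)) / (max(relief) - min(relief))
    elev <- 1830 * relief
    dzdx <- cbind(elev[, 2] - elev[, 1],
                  (elev[, -(1:2), drop = FALSE] -
                     elev[, seq_len(nc - 2), drop = FALSE]) / 2,
                  elev[, nc] - elev[, nc - 1]) / scenario$dx
    dzdy <- rbind(elev[2, ] - elev[1, ],
                  (elev[-(1:2), , drop = FALSE] -
                     elev[seq_len(nr - 2), , drop = FALSE]) / 2,
                  elev[nr, ] - elev[nr - 1, ]) / scenario$dx
    slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  })
  mk <- function(v, sem) raster_grid(v, dx = scenario$dx, semantic = sem)
  list(elevation = mk(elev, "elevation m"),
       slope = mk(slope, "slope deg"),
       relief = mk(relief, "relief 0-1"))
}

#' Generate monthly climate stacks
#'
#' Monthly temperature, precipitation and solar radiation over the scenario
#' years: per-variable annual mean plus a terrain-following spatial gradient,
#' a seasonal sinusoid (temperature and radiation peak in July, precipitation
#' in June, emulating a monsoon regime), a linear interannual trend, and
#' i.i.d. Gaussian pixel-month noise. Precipitation noise is proportional to
#' the local seasonal level (`sd` applies at the annual-mean month), which
#' matches the roughly constant coefficient of variation of monthly
#' precipitation records and keeps monthly totals positive; the floor at
#' 0 mm is retained as a hard guarantee.
#'
#' @param scenario a [nep_scenario()].
#' @param terrain optional precomputed [scenario_terrain()] result.
#' @return list of three monthly `grid_stack`s: `T` (degC), `R` (mm),
#'   `SOL` (MJ m-2).
#' @export
generate_climate <- function(scenario, terrain = scenario_terrain(scenario)) {
  nr <- scenario$shape[1]; nc <- scenario$shape[2]
  ti <- scenario_month_index(scenario)
  nt <- nrow(ti)
  relief <- terrain$relief$values
  peaks <- c(T = 7, R = 6, SOL = 7)
  out <- list()
  streams <- c(T = 11L, R = 12L, SOL = 13L)
  for (v in c("T", "R", "SOL")) {
    p <- scenario$climate_params[[v]]
    base <- p$mean + p$grad * (relief - mean(relief))
    season <- p$amp * cos(2 * pi * (ti$month - peaks[[v]]) / 12)
    tr_yr <- p$trend * (ti$year - scenario$years[1])
    arr <- withr::with_seed(sub_seed(scenario, streams[[v]]), {
      a <- array(stats::rnorm(nr * nc * nt), c(nr, nc, nt))
      for (k in seq_len(nt)) {
        level <- base + season[k] + tr_yr[k]
        sd_k <- if (v == "R") p$sd * pmax(level, 0) / p$mean else p$sd
        a[, , k] <- a[, , k] * sd_k + level
      }
      a
    })
    if (v == "R") arr <- pmax(arr, 0)
    if (v == "SOL") arr <- pmax(arr, 0)
    sem <- c(T = "air temperature degC", R = "precipitation mm",
             SOL = "solar radiation MJ m-2")[[v]]
    out[[v]] <- grid_stack(arr, template = terrain$relief, time_index = ti,
                           semantic = sem)
  }
  out
}

#' Generate NDVI and a vegetation-type map
#'
#' NDVI is `clip(baseline_field + a * z(T) + b * z(R) + noise, -0.2, 1)`
#' where `z()` standardizes the monthly climate over the whole stack, so
#' greenness co-varies with warm and wet anomalies. The vegetation-type map
#' cuts the terrain into three classes (1 = broadleaf forest on high relief,
#' 2 = shrub/grassland, 3 = cropland plains).
#'
#' @param scenario a [nep_scenario()].
#' @param climate output of [generate_climate()] (needed for coupling).
#' @param terrain optional precomputed terrain.
#' @return list with monthly `ndvi` `grid_stack` and `vegtype` `raster_grid`.
#' @export
generate_vegetation <- function(scenario, climate,
                                terrain = scenario_terrain(scenario)) {
  p <- scenario$ndvi_params
  zt <- scale_array(climate$T$values)
  zr <- scale_array(climate$R$values)
  nt <- dim(zt)[3]
  base <- p$baseline - p$relief / 2 + p$relief * terrain$relief$values
  ndvi <- withr::with_seed(sub_seed(scenario, 21L), {
    a <- p$a * zt + p$b * zr +
      array(stats::rnorm(length(zt), sd = p$sd), dim(zt))
    for (k in seq_len(nt)) a[, , k] <- a[, , k] + base
    a
  })
  ndvi <- pmin(pmax(ndvi, -0.2), 1)
  if (stats::sd(ndvi) == 0)
    warning("generated NDVI is constant; degenerate for correlation analyses")
  veg <- matrix(3L, scenario$shape[1], scenario$shape[2])
  veg[terrain$relief$values > 0.30] <- 2L
  veg[terrain$relief$values > 0.55] <- 1L
  list(ndvi = grid_stack(ndvi, template = terrain$relief,
                         time_index = climate$T$time_index,
                         semantic = "NDVI"),
       vegtype = raster_grid(veg, dx = scenario$dx,
                             semantic = "vegetation type code"))
}

scale_array <- function(a) (a - mean(a)) / stats::sd(a)

#' Generate stratified driver layers with known effects
#'
#' Builds the scenario's driver layers plus a synthetic NEP-like response
#' surface equal to the sum of per-stratum (categorical) and linear
#' (continuous) effects plus Gaussian noise, and a truth record of every
#' injected effect. Categorical layers are spatially coherent (quantile cuts
#' of smooth random fields), so strata are contiguous patches with balanced
#' sizes; a stratum that ends up empty is an error (cannot happen with
#' quantile cuts unless the field is degenerate).
#'
#' @param scenario a [nep_scenario()].
#' @param terrain optional precomputed terrain (supplies elevation/slope).
#' @return list with `drivers` (named list of `raster_grid`; categorical
#'   layers carry integer codes `1..L`), `response` (`raster_grid`,
#'   g C m-2 a-1), and `truth` (baseline, per-driver effects, expected
#'   stratum means for categorical drivers, noise sd).
#' @export
generate_drivers <- function(scenario, terrain = scenario_terrain(scenario)) {
  nr <- scenario$shape[1]; nc <- scenario$shape[2]
  dp <- scenario$driver_params
  rp <- scenario$response_params
  drivers <- list()
  contrib <- matrix(0, nr, nc)
  truth <- list(baseline = rp$baseline, noise_sd = rp$noise_sd,
                effects = list(), stratum_means = list())
  stream <- 30L
  for (nm in names(dp)) {
    d <- dp[[nm]]
    stream <- stream + 1L
    if (identical(d$type, "continuous")) {
      field <- switch(nm,
        elevation = terrain$elevation$values,
        slope = terrain$slope$values,
        withr::with_seed(sub_seed(scenario, stream), {
          f <- smooth_field(nr, nc, 6L)
          # urbanization surfaces concentrate in the low-relief northeast
          f * (1 - terrain$relief$values)
        }))
      rng <- range(field)
      unit <- if (diff(rng) > 0) (field - rng[1]) / diff(rng) else field * 0
      contrib <- contrib + d$beta * unit
      truth$effects[[nm]] <- list(type = "continuous", beta = d$beta)
      drivers[[nm]] <- raster_grid(field, dx = scenario$dx, semantic = nm)
    } else {
      if (length(d$effects) != d$L)
        stop("driver ", nm, ": effects length must equal L")
      codes <- withr::with_seed(sub_seed(scenario, stream), {
        f <- smooth_field(nr, nc, 5L)
        qs <- stats::quantile(f, probs = seq(0, 1, length.out = d$L + 1))
        as.integer(cut(f, breaks = unique(qs), include.lowest = TRUE))
      })
      if (length(unique(as.vector(codes))) < d$L)
        stop("driver ", nm, ": a stratum has zero pixels (degenerate field)")
      contrib <- contrib + matrix(d$effects[codes], nr, nc)
      truth$effects[[nm]] <- list(type = "categorical", L = d$L,
                                  effects = d$effects)
      truth$stratum_means[[nm]] <- rp$baseline + d$effects
      drivers[[nm]] <- raster_grid(matrix(codes, nr, nc), dx = scenario$dx,
                                   semantic = paste(nm, "code"))
    }
  }
  resp <- withr::with_seed(sub_seed(scenario, 60L),
    rp$baseline + contrib +
      matrix(stats::rnorm(nr * nc, sd = rp$noise_sd), nr, nc))
  list(drivers = drivers,
       response = raster_grid(resp, dx = scenario$dx,
                              semantic = "synthetic NEP g C m-2 a-1"),
       truth = truth)
}

#' Generate an annual NEP stack with an injected linear trend
#'
#' Direct generator for trend-recovery experiments: every pixel's annual
#' series is `baseline + slope * (year_index - 1) + N(0, noise_sd)`, with the
#' injected slope recorded as truth.
#'
#' @param shape grid dims `c(nrow, ncol)`.
#' @param years year vector.
#' @param slope injected trend, g C m-2 a-1 per year.
#' @param noise_sd Gaussian interannual noise sd (g C m-2 a-1).
#' @param baseline mean level (g C m-2 a-1).
#' @param seed integer seed.
#' @param dx pixel size in metres.
#' @return list with annual `grid_stack` `nep` and `truth$slope`.
#' @export
generate_trend_stack <- function(shape, years, slope, noise_sd,
                                 baseline = 380, seed = 1L, dx = 1000) {
  ny <- length(years)
  arr <- withr::with_seed(as.integer(seed), {
    a <- array(stats::rnorm(prod(shape) * ny, sd = noise_sd),
               c(shape[1], shape[2], ny))
    for (k in seq_len(ny)) a[, , k] <- a[, , k] + baseline + slope * (k - 1)
    a
  })
  list(nep = grid_stack(arr, time_index = data.frame(year = years), dx = dx,
                        semantic = "NEP g C m-2 a-1"),
       truth = list(slope = slope, noise_sd = noise_sd, baseline = baseline))
}

#' Sample series with a prescribed second-order partial correlation
#'
#' Draws `n` observations of four jointly Gaussian variables
#' `(y, x, c1, c2)` whose partial correlation between `y` and `x` given
#' `(c1, c2)` equals `rho` and whose remaining partial correlations are zero,
#' by constructing the precision matrix directly (off-diagonal
#' `-rho` between `y` and `x`) and sampling from its inverse.
#'
#' @param n sample size.
#' @param rho target partial correlation in `(-1, 1)`.
#' @param seed integer seed.
#' @return `n x 4` matrix with columns `y, x, c1, c2`; attribute
#'   `partial_rho` records the truth.
#' @export
generate_partial_structure <- function(n, rho, seed = 1L) {
  stopifnot(abs(rho) < 1)
  omega <- diag(4)
  omega[1, 2] <- omega[2, 1] <- -rho
  sigma <- solve(omega)
  L <- chol(sigma)
  z <- withr::with_seed(as.integer(seed),
                        matrix(stats::rnorm(n * 4), n, 4))
  x <- z %*% L
  colnames(x) <- c("y", "x", "c1", "c2")
  attr(x, "partial_rho") <- rho
  x
}
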