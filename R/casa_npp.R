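#' CASA parameter table
#'
#' Per-vegetation-type constants of the light-use-efficiency model. All model
#' constants live here (not in code) so they can be re-calibrated without
#' touching the implementation: NDVI at bare soil (`ndvi_min`, FPAR = 0
#' at or below it), NDVI at canopy saturation (`ndvi_max`), and the maximal
#' light-use efficiency `emax` (g C MJ-1). `fpar_max` caps FPAR at canopy
#' saturation; `par_fraction` is the photosynthetically active fraction of
#' total incoming solar radiation.
#'
#' @param table data.frame with columns `code`, `name`, `ndvi_min`,
#'   `ndvi_max`, `emax`; the default covers the three synthetic vegetation
#'   classes with classic CASA-style values.
#' @param fpar_max FPAR cap (default 0.95).
#' @param par_fraction PAR fraction of solar radiation (default 0.5).
#' @return list of class `casa_params`.
#' @export
casa_params <- function(table = data.frame(
                          code = c(1L, 2L, 3L),
                          name = c("broadleaf_forest", "shrub_grassland",
                                   "cropland"),
                          ndvi_min = c(0.05, 0.05, 0.05),
                          ndvi_max = c(0.90, 0.84, 0.80),
                          emax = c(0.985, 0.542, 0.542)),
                        fpar_max = 0.95, par_fraction = 0.5) {
  stopifnot(all(c("code", "ndvi_min", "ndvi_max", "emax") %in% names(table)),
            all(table$ndvi_max > table$ndvi_min),
            fpar_max > 0, fpar_max <= 1, par_fraction > 0, par_fraction <= 1)
  structure(list(table = table, fpar_max = fpar_max,
                 par_fraction = par_fraction), class = "casa_params")
}

check_veg_codes <- function(vegtype, params) {
  codes <- unique(stats::na.omit(as.vector(vegtype)))
  unknown <- setdiff(codes, params$table$code)
  if (length(unknown))
    stop("unknown vegetation code(s) ", paste(unknown, collapse = ", "),
         "; known codes: ", paste(params$table$code, collapse = ", "))
}

veg_lookup <- function(vegtype, params, col) {
  idx <- match(as.vector(vegtype), params$table$code)
  matrix(params$table[[col]][idx], nrow(vegtype), ncol(vegtype))
}

as_values <- function(x) {
  if (inherits(x, c("raster_grid", "grid_stack"))) x$values else x
}

#' Fraction of absorbed photosynthetically active radiation
#'
#' FPAR rises linearly with NDVI between the vegetation type's bare-soil
#' minimum (FPAR = 0) and saturation maximum (FPAR = `fpar_max`), clamped to
#' that range — the standard NDVI-based CASA formulation.
#'
#' @param ndvi NDVI array/matrix/`grid_stack` in `[-1, 1]`.
#' @param vegtype vegetation-code matrix/`raster_grid`.
#' @param params a [casa_params()].
#' @return FPAR with the shape of `ndvi`, in `[0, fpar_max]`.
#' @export
compute_fpar <- function(ndvi, vegtype, params = casa_params()) {
  nd <- as_values(ndvi); vt <- as_values(vegtype)
  if (any(nd < -1 | nd > 1, na.rm = TRUE)) stop("NDVI outside [-1, 1]")
  check_veg_codes(vt, params)
  lo <- veg_lookup(vt, params, "ndvi_min")
  hi <- veg_lookup(vt, params, "ndvi_max")
  f <- function(slice) pmin(pmax((slice - lo) / (hi - lo), 0), 1) *
    params$fpar_max
  out <- if (length(dim(nd)) == 3) {
    a <- nd
    for (k in seq_len(dim(nd)[3])) a[, , k] <- f(nd[, , k])
    a
  } else f(nd)
  out
}

#' Absorbed photosynthetically active radiation
#'
#' `APAR = SOL * FPAR * par_fraction`: incoming solar radiation times the
#' photosynthetically active fraction times the canopy-absorbed fraction.
#'
#' @param sol solar radiation (MJ m-2 per month), same shape as `fpar`.
#' @param fpar output of [compute_fpar()].
#' @param params a [casa_params()].
#' @return APAR in MJ m-2 per month.
#' @export
compute_apar <- function(sol, fpar, params = casa_params()) {
  s <- as_values(sol)
  if (any(s < 0, na.rm = TRUE)) stop("negative solar radiation")
  s * as_values(fpar) * params$par_fraction
}

#' Optimum-month temperature per pixel
#'
#' The CASA temperature-stress reference: the monthly mean air temperature of
#' the month whose (climatological mean) NDVI is highest at each pixel.
#'
#' @param T_monthly monthly temperature array/`grid_stack`.
#' @param ndvi monthly NDVI array/`grid_stack` with the same time index.
#' @return matrix of optimum temperatures (degC).
#' @export
optimum_temperature <- function(T_monthly, ndvi) {
  ta <- as_values(T_monthly); na <- as_values(ndvi)
  stopifnot(identical(dim(ta), dim(na)))
  nt <- dim(ta)[3]
  months <- rep_len(1:12, nt)
  nr <- dim(ta)[1]; nc <- dim(ta)[2]
  ndvi_clim <- array(NA_real_, c(nr, nc, 12))
  t_clim <- array(NA_real_, c(nr, nc, 12))
  for (m in 1:12) {
    sel <- which(months == m)
    ndvi_clim[, , m] <- apply(na[, , sel, drop = FALSE], c(1, 2), mean)
    t_clim[, , m] <- apply(ta[, , sel, drop = FALSE], c(1, 2), mean)
  }
  best <- apply(ndvi_clim, c(1, 2), function(v)
    if (all(is.na(v))) NA_integer_ else which.max(v))
  out <- matrix(NA_real_, nr, nc)
  for (m in 1:12) {
    sel <- !is.na(best) & best == m
    out[sel] <- t_clim[, , m][sel]
  }
  out
}

#' Monthly potential evapotranspiration (Thornthwaite)
#'
#' Temperature-only monthly PET used as the atmospheric water demand in the
#' water-stress scalar: `PET = 16 (10 T / I)^a` mm per month, with the annual
#' heat index `I = sum((T_m/5)^1.514)` over months with `T_m > 0`, and zero
#' PET for months at or below 0 degC.
#'
#' @param T_monthly array `[row, col, 12]` of one year's monthly temperature.
#' @return array of monthly PET (mm).
#' @export
pet_thornthwaite <- function(T_monthly) {
  tp <- pmax(T_monthly, 0)
  I <- apply((tp / 5)^1.514, c(1, 2), sum)
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  pet <- T_monthly
  for (m in seq_len(dim(T_monthly)[3])) {
    pet[, , m] <- ifelse(T_monthly[, , m] > 0 & I > 0,
                         16 * (10 * T_monthly[, , m] / I)^a, 0)
  }
  pet
}

#' Light-use efficiency
#'
#' `eps = T1 * T2 * W * emax` with the classic CASA stress scalars:
#' `T1 = 0.8 + 0.02 Topt - 0.0005 Topt^2` (quadratic in the optimum-month
#' temperature, zeroed below -10 degC), the logistic asymmetry penalty
#' `T2 = 1.1814 / ((1 + exp(0.2 (Topt - 10 - T))) (1 + exp(0.3 (T - Topt
#' - 10))))`, and the water stress `W = 0.5 + 0.5 * min(1, R / PET)` (supply/
#' demand ratio with Thornthwaite PET as demand; `W = 1` where demand is
#' zero). All scalars are clamped to `[0, 1]`, so `eps` lies in
#' `[0, emax]`.
#'
#' @param T_monthly monthly temperature array/`grid_stack` (degC).
#' @param R_monthly monthly precipitation array/`grid_stack` (mm).
#' @param vegtype vegetation-code matrix/`raster_grid`.
#' @param topt optimum-month temperature matrix ([optimum_temperature()]).
#' @param params a [casa_params()].
#' @return list with `lue` array (g C MJ-1) and the stress arrays
#'   `t1`, `t2`, `w`.
#' @export
compute_lue <- function(T_monthly, R_monthly, vegtype, topt,
                        params = casa_params()) {
  ta <- as_values(T_monthly); ra <- as_values(R_monthly)
  vt <- as_values(vegtype)
  check_veg_codes(vt, params)
  emax <- veg_lookup(vt, params, "emax")
  nt <- dim(ta)[3]
  if (nt %% 12 != 0) stop("monthly stack length must be a multiple of 12")
  t1m <- pmin(pmax(0.8 + 0.02 * topt - 0.0005 * topt^2, 0), 1)
  t1 <- ta; t2 <- ta; w <- ta
  pet <- array(NA_real_, dim(ta))
  for (y in seq_len(nt / 12)) {
    sel <- (y - 1) * 12 + 1:12
    pet[, , sel] <- pet_thornthwaite(ta[, , sel, drop = FALSE])
  }
  for (k in seq_len(nt)) {
    tk <- ta[, , k]
    t1[, , k] <- ifelse(tk < -10, 0, t1m)
    t2[, , k] <- pmin(pmax(
      1.1814 / ((1 + exp(0.2 * (topt - 10 - tk))) *
                  (1 + exp(0.3 * (tk - topt - 10)))), 0), 1)
    ratio <- ifelse(pet[, , k] > 0, pmin(ra[, , k] / pet[, , k], 1), 1)
    w[, , k] <- 0.5 + 0.5 * ratio
  }
  lue <- t1 * t2 * w
  for (k in seq_len(nt)) lue[, , k] <- lue[, , k] * emax
  list(lue = lue, t1 = t1, t2 = t2, w = w)
}

#' Estimate NPP with the light-use-efficiency model
#'
#' Core product equation `NPP(x, t) = APAR(x, t) * eps(x, t)` applied per
#' pixel and month; annual NPP is the exact sum of the year's 12 monthly
#' values. Months with NDVI at or below the type's bare-soil minimum
#' contribute zero (never negative) NPP. Nodata in any input propagates.
#'
#' @param climate list of monthly `grid_stack`s `T`, `R`, `SOL`
#'   (as from [generate_climate()]).
#' @param ndvi monthly NDVI `grid_stack` on the same time index.
#' @param vegtype vegetation-code `raster_grid`.
#' @param params a [casa_params()].
#' @return object of class `npp_cube`: arrays `npp_monthly`, `apar`, `lue`
#'   (per month), `npp_annual` `[row, col, year]`, plus `fpar`, time
#'   indexes and the shared georeference.
#' @export
compute_npp <- function(climate, ndvi, vegtype, params = casa_params()) {
  if (!is.null(climate$T$time_index) && !is.null(ndvi$time_index) &&
      !identical(climate$T$time_index, ndvi$time_index))
    stop("time index mismatch between climate and NDVI stacks")
  fpar <- compute_fpar(ndvi, vegtype, params)
  apar <- compute_apar(climate$SOL, fpar, params)
  topt <- optimum_temperature(climate$T, ndvi)
  st <- compute_lue(climate$T, climate$R, vegtype, topt, params)
  npp_m <- apar * st$lue
  ti <- climate$T$time_index
  years <- unique(ti$year)
  nr <- dim(npp_m)[1]; nc <- dim(npp_m)[2]
  npp_a <- array(NA_real_, c(nr, nc, length(years)))
  for (j in seq_along(years)) {
    sel <- which(ti$year == years[j])
    npp_a[, , j] <- apply(npp_m[, , sel, drop = FALSE], c(1, 2), sum)
  }
  structure(list(npp_monthly = npp_m, npp_annual = npp_a, apar = apar,
                 lue = st$lue, fpar = fpar, topt = topt,
                 time_index = ti, years = years,
                 transform = climate$T$transform, crs = climate$T$crs),
            class = "npp_cube")
}

#' Validate estimated NPP against a reference layer
#'
#' Samples `n_points` valid common pixels without replacement (seeded),
#' extracts both layers' values and reports the Pearson correlation, its
#' square and the two-sided p-value from the t transform with `n - 2`
#' degrees of freedom.
#'
#' @param estimated,reference annual NPP matrices or `raster_grid`s on the
#'   same geometry.
#' @param n_points number of sample points (default 100).
#' @param seed integer seed for the sample.
#' @return list of class `validation_stats` with `r`, `r2`, `p`, `n`.
#' @export
validate_npp <- function(estimated, reference, n_points = 100, seed = 1L) {
  e <- as_values(estimated); r <- as_values(reference)
  stopifnot(identical(dim(e), dim(r)))
  valid <- which(!is.na(e) & !is.na(r))
  if (length(valid) < n_points)
    stop("only ", length(valid), " valid common pixels; need ", n_points)
  idx <- withr::with_seed(as.integer(seed), sample(valid, n_points))
  ct <- stats::cor.test(e[idx], r[idx], method = "pearson")
  structure(list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
                 p = ct$p.value, n = n_points),
            class = "validation_stats")
}
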