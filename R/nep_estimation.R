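#' Soil heterotrophic respiration (empirical)
#'
#' Monthly Rh from air temperature and precipitation:
#' `Rh = 0.22 * (exp(0.0913 T) + ln(0.3145 R) + 1) * 30 * 0.465`
#' in g C m-2 month-1, with T in degC and R in mm. The day factor 30 and the
#' carbon fraction 46.5% are applied exactly as printed constants. Cells with
#' `R <= 0` (logarithm undefined) are masked for that month and counted in
#' the `n_nonpositive_precip` attribute rather than silently zeroed.
#'
#' @param T_air temperature (degC): scalar, matrix, array or `grid_stack`.
#' @param R_precip precipitation (mm), same shape.
#' @return Rh with the shape of the inputs (g C m-2 month-1); attribute
#'   `n_nonpositive_precip` holds the count of masked cells.
#' @export
compute_rh <- function(T_air, R_precip) {
  ta <- as_values(T_air); ra <- as_values(R_precip)
  if (!identical(dim(ta), dim(ra)) && !(is.null(dim(ta)) && is.null(dim(ra))))
    stop("temperature and precipitation shapes differ")
  bad <- !is.na(ra) & ra <= 0
  ra[bad] <- NA
  rh <- 0.22 * (exp(0.0913 * ta) + log(0.3145 * ra) + 1) * 30 * 0.465
  attr(rh, "n_nonpositive_precip") <- sum(bad)
  rh
}

#' Net ecosystem productivity
#'
#' `NEP(x, t) = NPP(x, t) - Rh(x, t)` per pixel and month; annual NEP is the
#' exact sum of the year's 12 monthly values. Positive NEP marks a carbon
#' sink, negative a carbon source.
#'
#' @param npp an `npp_cube` from [compute_npp()].
#' @param rh_monthly monthly Rh array matching `npp$npp_monthly`
#'   (from [compute_rh()]).
#' @return object of class `nep_cube`: `rh_monthly`, `nep_monthly`,
#'   `nep_annual` `[row, col, year]`, `rh_annual`, plus time indexes and
#'   georeference carried from the NPP cube.
#' @export
compute_nep <- function(npp, rh_monthly) {
  rh <- as_values(rh_monthly)
  if (!identical(dim(npp$npp_monthly), dim(rh)))
    stop("NPP and Rh shapes differ: ",
         paste(dim(npp$npp_monthly), collapse = "x"), " vs ",
         paste(dim(rh), collapse = "x"))
  nep_m <- npp$npp_monthly - rh
  ti <- npp$time_index
  years <- npp$years
  nr <- dim(nep_m)[1]; nc <- dim(nep_m)[2]
  nep_a <- array(NA_real_, c(nr, nc, length(years)))
  rh_a <- nep_a
  for (j in seq_along(years)) {
    sel <- which(ti$year == years[j])
    nep_a[, , j] <- apply(nep_m[, , sel, drop = FALSE], c(1, 2), sum)
    rh_a[, , j] <- apply(rh[, , sel, drop = FALSE], c(1, 2), sum)
  }
  structure(list(rh_monthly = rh, nep_monthly = nep_m, nep_annual = nep_a,
                 rh_annual = rh_a, time_index = ti, years = years,
                 transform = npp$transform, crs = npp$crs),
            class = "nep_cube")
}

#' Classify pixels as carbon sink / source / neutral
#'
#' `NEP > 0` is a carbon sink, `NEP < 0` a carbon source; exact zero is
#' classified neutral (the strict inequalities define only sink and source).
#'
#' @param nep_annual annual NEP matrix or `raster_grid` (g C m-2 a-1).
#' @return integer matrix: `1` sink, `-1` source, `0` neutral, `NA` nodata;
#'   attribute `labels` maps codes to names.
#' @export
classify_sink_source <- function(nep_annual) {
  v <- as_values(nep_annual)
  out <- sign(v)
  mode(out) <- "integer"
  attr(out, "labels") <- c(`-1` = "source", `0` = "neutral", `1` = "sink")
  out
}

#' Regional carbon budget
#'
#' Aggregates per-pixel NEP (g C m-2 a-1) to regional totals in Tg C a-1
#' (1 Tg = 1e12 g) using the pixel area implied by the georeference (assumed
#' equal-area; a non-metric CRS only changes the area constant). Totals are
#' split by sign: `sink_total` over NEP > 0 pixels, `source_total` (negative)
#' over NEP < 0 pixels, and their exact sum `net_total`.
#'
#' @param nep_annual annual NEP matrix or `raster_grid`.
#' @param transform georeference list (`dx`, `dy`, in metres) or a
#'   `raster_grid`/`grid_stack` carrying one; ignored if `nep_annual` is a
#'   `raster_grid`.
#' @return list of class `regional_budget`: `sink_total`, `source_total`,
#'   `net_total` (Tg C a-1), `sink_area_fraction`, `source_area_fraction`,
#'   `neutral_area_fraction`, `mean_nep` (g C m-2 a-1), `n_valid`,
#'   `pixel_area_m2`.
#' @export
aggregate_regional <- function(nep_annual, transform = NULL) {
  if (inherits(nep_annual, "raster_grid")) {
    transform <- nep_annual$transform
    v <- nep_annual$values
  } else {
    v <- as_values(nep_annual)
    if (inherits(transform, c("raster_grid", "grid_stack")))
      transform <- transform$transform
    if (is.null(transform)) stop("a georeference is required for areas")
  }
  area <- transform$dx * transform$dy
  valid <- !is.na(v)
  n <- sum(valid)
  vv <- v[valid]
  sink <- sum(vv[vv > 0]) * area / 1e12
  source <- sum(vv[vv < 0]) * area / 1e12
  structure(list(
    sink_total = sink, source_total = source, net_total = sink + source,
    sink_area_fraction = if (n) sum(vv > 0) / n else NA_real_,
    source_area_fraction = if (n) sum(vv < 0) / n else NA_real_,
    neutral_area_fraction = if (n) sum(vv == 0) / n else NA_real_,
    mean_nep = if (n) mean(vv) else NA_real_,
    n_valid = n, pixel_area_m2 = area), class = "regional_budget")
}

#' @export
print.regional_budget <- function(x, ...) {
  cat(sprintf(
    "regional budget: sink %.4f Tg C a-1, source %.4f Tg C a-1, net %.4f\n",
    x$sink_total, x$source_total, x$net_total))
  cat(sprintf("  sink area %.2f%%, mean NEP %.2f g C m-2 a-1 (n = %d)\n",
              100 * x$sink_area_fraction, x$mean_nep, x$n_valid))
  invisible(x)
}
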