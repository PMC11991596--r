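#' Second-order partial correlation
#'
#' Correlation between `y` and `x` with the linear effects of two control
#' series removed, computed from the inverse of the 4-variable correlation
#' matrix: `r = -W[y,x] / sqrt(W[y,y] * W[x,x])` with `W` the precision
#' (inverse correlation) matrix. Significance is the two-sided t-test
#' `t = r * sqrt((n - 4) / (1 - r^2))` on `n - 4` degrees of freedom (two
#' controls spend two extra degrees of freedom).
#'
#' @param y,x numeric series of common length `n >= 5`, non-constant.
#' @param controls two-column matrix (or list of two series) of controls.
#' @return list with `r`, `p`, `n`; `r = NA` with a `reason` element when
#'   the correlation matrix is singular (collinear inputs).
#' @export
partial_correlation <- function(y, x, controls) {
  if (is.list(controls) && !is.data.frame(controls))
    controls <- do.call(cbind, controls)
  controls <- as.matrix(controls)
  stopifnot(ncol(controls) == 2)
  n <- length(y)
  if (length(x) != n || nrow(controls) != n) stop("series lengths differ")
  if (n < 5) stop("need n >= 5 for a second-order partial correlation")
  m <- cbind(y = y, x = x, controls)
  if (any(apply(m, 2, stats::sd) == 0))
    return(list(r = NA_real_, p = NA_real_, n = n,
                reason = "constant input series"))
  cm <- stats::cor(m)
  # perfect dependence between y and x: the residual correlation is +/-1
  # but the 4-variable matrix is singular, so handle it before inverting
  if (abs(cm[1, 2]) >= 1 - 1e-12)
    return(list(r = sign(cm[1, 2]), p = 0, n = n))
  w <- tryCatch(solve(cm), error = function(e) NULL)
  if (is.null(w) || !all(is.finite(w)))
    return(list(r = NA_real_, p = NA_real_, n = n,
                reason = "singular correlation matrix (collinear inputs)"))
  r <- -w[1, 2] / sqrt(w[1, 1] * w[2, 2])
  r <- min(max(r, -1), 1)
  df <- n - 4
  p <- if (abs(r) >= 1) 0 else
    2 * stats::pt(abs(r) * sqrt(df / (1 - r^2)), df, lower.tail = FALSE)
  list(r = r, p = p, n = n)
}

#' Multiple correlation of a response on three predictors
#'
#' `R = sqrt(R^2)` of the least-squares regression of `y` on the three
#' columns of `X` with intercept, tested with
#' `F = (R^2 / k) / ((1 - R^2) / (n - k - 1))`, `k = 3`.
#'
#' @param y numeric response series, `n >= 6`.
#' @param X matrix with three predictor columns.
#' @return list with `R`, `r2`, `p`, `n`; `NA` with `reason` on collinear
#'   predictors.
#' @export
multiple_correlation <- function(y, X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == 3)
  n <- length(y)
  if (nrow(X) != n) stop("series lengths differ")
  if (n < 6) stop("need n >= 6 for the three-predictor multiple correlation")
  if (stats::sd(y) == 0)
    return(list(R = NA_real_, r2 = NA_real_, p = NA_real_, n = n,
                reason = "constant response"))
  Xc <- cbind(1, X)
  if (qr(Xc)$rank < 4)
    return(list(R = NA_real_, r2 = NA_real_, p = NA_real_, n = n,
                reason = "collinear predictors"))
  fit <- stats::lm.fit(Xc, y)
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  r2 <- min(max(1 - sse / sst, 0), 1)
  k <- 3
  p <- if (r2 >= 1) 0 else
    stats::pf((r2 / k) / ((1 - r2) / (n - k - 1)), k, n - k - 1,
              lower.tail = FALSE)
  list(R = sqrt(r2), r2 = r2, p = p, n = n)
}

climate_type_levels <- c("temperature_driven", "precipitation_driven",
                         "solar_radiation_driven",
                         "temperature_precipitation_driven",
                         "temperature_solar_driven",
                         "precipitation_solar_driven",
                         "strongly_driven_by_T_P_S",
                         "weakly_driven_by_T_P_S",
                         "non_climatic")

#' Nine-class climate-driving typology
#'
#' Assigns one of nine driving types from the per-pixel partial-correlation
#' significances and the multiple-correlation significance. The gate is the
#' multiple correlation: `p_multiple >= alpha` means no detectable joint
#' climate control (`non_climatic`). Within the gate, the set of individually
#' significant partials (`p < alpha`) decides: one -> that single factor's
#' type; two -> the pairwise type; all three -> `strongly_driven_by_T_P_S`;
#' none -> `weakly_driven_by_T_P_S` (jointly but not individually
#' significant). This decision table is a reconstruction of commonly used
#' criteria (see the methods vignette); the labels partition every valid
#' pixel.
#'
#' @param p_partial length-3 vector of partial-correlation p-values, in the
#'   order temperature, precipitation, solar radiation.
#' @param p_multiple multiple-correlation p-value.
#' @param alpha significance level (default 0.05).
#' @return one of the nine type labels (character).
#' @export
classify_driver_type <- function(p_partial, p_multiple, alpha = 0.05) {
  stopifnot(length(p_partial) == 3)
  if (is.na(p_multiple) || any(is.na(p_partial))) return(NA_character_)
  if (p_multiple >= alpha) return("non_climatic")
  sig <- p_partial < alpha
  key <- paste(ifelse(sig, "1", "0"), collapse = "")
  switch(key,
         "100" = "temperature_driven",
         "010" = "precipitation_driven",
         "001" = "solar_radiation_driven",
         "110" = "temperature_precipitation_driven",
         "101" = "temperature_solar_driven",
         "011" = "precipitation_solar_driven",
         "111" = "strongly_driven_by_T_P_S",
         "000" = "weakly_driven_by_T_P_S")
}

#' Annual climate series from monthly stacks
#'
#' Collapses monthly climate to the annual series entering the correlation
#' analyses: mean annual temperature, total annual precipitation, total
#' annual solar radiation.
#'
#' @param climate list of monthly `grid_stack`s `T`, `R`, `SOL`.
#' @return list of `[row, col, year]` arrays `T`, `R`, `SOL` plus `years`.
#' @export
annual_climate <- function(climate) {
  ti <- climate$T$time_index
  years <- unique(ti$year)
  collapse <- function(a, fun) {
    out <- array(NA_real_, c(dim(a)[1], dim(a)[2], length(years)))
    for (j in seq_along(years)) {
      sel <- which(ti$year == years[j])
      out[, , j] <- apply(a[, , sel, drop = FALSE], c(1, 2), fun)
    }
    out
  }
  list(T = collapse(climate$T$values, mean),
       R = collapse(climate$R$values, sum),
       SOL = collapse(climate$SOL$values, sum),
       years = years)
}

#' Pixel-wise climate attribution map
#'
#' For every valid pixel: the three second-order partial correlations of
#' annual NEP with temperature, precipitation and solar radiation (each
#' controlling the other two), the multiple correlation of NEP on all three,
#' their significances, and the nine-class driving type. Pixels with any
#' masked year or a degenerate (constant/collinear) series are dropped from
#' the proportions (complete-case) and counted in `n_dropped`.
#'
#' @param nep_annual_stack annual NEP `grid_stack` or array.
#' @param climate_annual list of annual arrays `T`, `R`, `SOL`
#'   (from [annual_climate()]).
#' @param alpha significance level for typing (default 0.05).
#' @return object of class `attribution_map`: per-factor `r_partial` and
#'   `p_partial` matrices, `R_multiple`, `p_multiple`, `type` (integer codes
#'   into `levels`), `type_proportions`, `positive_fraction` and
#'   `significance_fractions` per factor (share of valid area with p < 0.01,
#'   0.01-0.05, >= 0.05), `n_valid`, `n_dropped`.
#' @export
attribution_map <- function(nep_annual_stack, climate_annual, alpha = 0.05) {
  a <- as_values(nep_annual_stack)
  nr <- dim(a)[1]; nc <- dim(a)[2]; ny <- dim(a)[3]
  stopifnot(identical(dim(climate_annual$T), dim(a)))
  Y <- matrix(a, nr * nc, ny)
  Tm <- matrix(climate_annual$T, nr * nc, ny)
  Pm <- matrix(climate_annual$R, nr * nc, ny)
  Sm <- matrix(climate_annual$SOL, nr * nc, ny)
  npix <- nr * nc
  r_par <- matrix(NA_real_, npix, 3,
                  dimnames = list(NULL, c("T", "P", "S")))
  p_par <- r_par
  R_mul <- rep(NA_real_, npix); p_mul <- R_mul
  type <- rep(NA_character_, npix)
  complete <- rowSums(is.na(cbind(Y, Tm, Pm, Sm))) == 0
  n_dropped <- 0L
  # One inversion of the 4-variable correlation matrix per pixel yields all
  # three second-order partials (-W[1,f]/sqrt(W11 Wff)) and the multiple
  # R^2 (1 - 1/W11) at once; identical to partial_correlation() /
  # multiple_correlation() applied per series (asserted in the tests).
  df_par <- ny - 4
  for (px in which(complete)) {
    m <- cbind(Y[px, ], Tm[px, ], Pm[px, ], Sm[px, ])
    if (any(apply(m, 2, stats::sd) == 0)) { n_dropped <- n_dropped + 1L; next }
    w <- tryCatch(solve(stats::cor(m)), error = function(e) NULL)
    if (is.null(w) || !all(is.finite(w)) || w[1, 1] < 1) {
      n_dropped <- n_dropped + 1L; next
    }
    for (f in 1:3) {
      r <- min(max(-w[1, f + 1] / sqrt(w[1, 1] * w[f + 1, f + 1]), -1), 1)
      r_par[px, f] <- r
      p_par[px, f] <- if (abs(r) >= 1) 0 else
        2 * stats::pt(abs(r) * sqrt(df_par / (1 - r^2)), df_par,
                      lower.tail = FALSE)
    }
    r2 <- min(max(1 - 1 / w[1, 1], 0), 1)
    R_mul[px] <- sqrt(r2)
    p_mul[px] <- if (r2 >= 1) 0 else
      stats::pf((r2 / 3) / ((1 - r2) / (ny - 4)), 3, ny - 4,
                lower.tail = FALSE)
    type[px] <- classify_driver_type(p_par[px, ], p_mul[px], alpha)
  }
  n_dropped <- n_dropped + sum(!complete)
  typef <- factor(type, levels = climate_type_levels)
  n_valid <- sum(!is.na(typef))
  prop <- table(typef) / max(n_valid, 1)
  sig_frac <- apply(p_par, 2, function(p) {
    p <- p[!is.na(p)]
    c(highly_significant = mean(p < 0.01),
      significant = mean(p >= 0.01 & p < 0.05),
      not_significant = mean(p >= 0.05))
  })
  structure(list(
    r_partial = lapply(1:3, function(f) matrix(r_par[, f], nr, nc)) |>
      stats::setNames(c("T", "P", "S")),
    p_partial = lapply(1:3, function(f) matrix(p_par[, f], nr, nc)) |>
      stats::setNames(c("T", "P", "S")),
    R_multiple = matrix(R_mul, nr, nc), p_multiple = matrix(p_mul, nr, nc),
    type = matrix(as.integer(typef), nr, nc), levels = climate_type_levels,
    type_proportions = stats::setNames(as.numeric(prop), names(prop)),
    positive_fraction = colMeans(r_par > 0, na.rm = TRUE),
    significance_fractions = sig_frac,
    n_valid = n_valid, n_dropped = n_dropped),
    class = "attribution_map")
}
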