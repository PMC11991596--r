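#' Least-squares trend of an annual series
#'
#' Closed-form univariate least-squares slope against the time index
#' `i = 1..n`:
#' `Slope = (n * sum(i * y) - sum(i) * sum(y)) / (n * sum(i^2) - sum(i)^2)`.
#' Significance comes from the regression F statistic
#' `F = r^2 (n - 2) / (1 - r^2)` on `(1, n - 2)` degrees of freedom. A
#' constant series (zero variance) gets slope 0 and p = 1 so maps stay
#' total; series shorter than 3 are rejected.
#'
#' @param series numeric vector of annual values (`NA`s are not allowed;
#'   drop or mask upstream).
#' @return named vector `c(slope, p)`.
#' @export
fit_trend <- function(series) {
  y <- as.numeric(series)
  if (anyNA(y)) stop("series contains NA; complete cases are required")
  n <- length(y)
  if (n < 3) stop("need at least 3 values, got ", n)
  res <- trend_matrix(matrix(y, nrow = 1))
  c(slope = res$slope[1], p = res$p[1])
}

# Vectorized closed-form trend over rows of Y (pixels x years).
trend_matrix <- function(Y) {
  n <- ncol(Y)
  i <- seq_len(n)
  si <- sum(i); sii <- sum(i^2)
  sy <- rowSums(Y)
  siy <- as.vector(Y %*% i)
  denom <- n * sii - si^2
  slope <- (n * siy - si * sy) / denom
  sst <- rowSums(Y^2) - sy^2 / n
  ssr <- slope^2 * (sii - si^2 / n)
  r2 <- ifelse(sst > 0, pmin(ssr / sst, 1), 0)
  Fst <- ifelse(r2 < 1, r2 * (n - 2) / (1 - r2), Inf)
  p <- ifelse(sst > 0, stats::pf(Fst, 1, n - 2, lower.tail = FALSE), 1)
  slope[sst == 0] <- 0
  list(slope = slope, p = p, r2 = r2, n = n)
}

trend_class_levels <- c("extremely_significant_increase",
                        "significant_increase", "stable",
                        "significant_decrease",
                        "extremely_significant_decrease")

#' Five-class trend significance classification
#'
#' Classifies a fitted trend per the rule set: extremely significant
#' increase (`p < 0.01`, slope > 0), significant increase
#' (`0.01 <= p < 0.05`, slope > 0), stable (`p >= 0.05` or slope = 0),
#' significant decrease and extremely significant decrease symmetrically.
#' Boundary p-values fall into the less-significant class.
#'
#' @param slope,p numeric vectors of equal length.
#' @return factor with the five trend levels (`NA` in -> `NA` out).
#' @export
classify_trend <- function(slope, p) {
  cls <- rep(NA_character_, length(slope))
  ok <- !is.na(slope) & !is.na(p)
  cls[ok] <- "stable"
  up <- ok & slope > 0 & p < 0.05
  dn <- ok & slope < 0 & p < 0.05
  cls[up] <- ifelse(p[up] < 0.01, "extremely_significant_increase",
                    "significant_increase")
  cls[dn] <- ifelse(p[dn] < 0.01, "extremely_significant_decrease",
                    "significant_decrease")
  factor(cls, levels = trend_class_levels)
}

#' Per-pixel trend map of annual NEP
#'
#' Fits the closed-form least-squares trend at every valid pixel of an
#' annual stack, tests it with the regression F-test, applies the five-class
#' rule and reports the area proportion of each class over valid pixels.
#' Pixels with any masked year are excluded (complete-case).
#'
#' @param nep_annual_stack annual `grid_stack` (or `[row, col, year]` array)
#'   with at least 3 layers.
#' @return object of class `trend_map`: matrices `slope`, `p`, `class`
#'   (integer codes into `levels`), `class_proportions` (named, sums to 1
#'   over valid pixels), `n`.
#' @export
trend_map <- function(nep_annual_stack) {
  a <- as_values(nep_annual_stack)
  stopifnot(length(dim(a)) == 3)
  ny <- dim(a)[3]
  if (ny < 3) stop("need >= 3 annual layers, got ", ny)
  nr <- dim(a)[1]; nc <- dim(a)[2]
  Y <- matrix(a, nr * nc, ny)
  complete <- rowSums(is.na(Y)) == 0
  slope <- rep(NA_real_, nr * nc); p <- slope
  if (any(complete)) {
    res <- trend_matrix(Y[complete, , drop = FALSE])
    slope[complete] <- res$slope
    p[complete] <- res$p
  }
  cls <- classify_trend(slope, p)
  prop <- table(cls) / sum(!is.na(cls))
  structure(list(slope = matrix(slope, nr, nc), p = matrix(p, nr, nc),
                 class = matrix(as.integer(cls), nr, nc),
                 levels = trend_class_levels,
                 class_proportions = stats::setNames(as.numeric(prop),
                                                     names(prop)),
                 n = ny),
            class = "trend_map")
}
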