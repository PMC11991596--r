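# Independent oracles: deliberately naive implementations used only to
# check the package's vectorized/closed-form routines.

# scalar transcription of the soil-respiration equation, one cell at a time
rh_scalar_oracle <- function(T_air, R_precip) {
  stopifnot(length(T_air) == length(R_precip))
  out <- numeric(length(T_air))
  for (i in seq_along(T_air)) {
    out[i] <- 0.22 * (exp(0.0913 * T_air[i]) + log(0.3145 * R_precip[i]) + 1) *
      30 * 0.465
  }
  out
}

# generic least-squares solver for the trend (normal equations via lm)
slope_lm_oracle <- function(y) {
  i <- seq_along(y)
  fit <- stats::lm(y ~ i)
  c(slope = unname(stats::coef(fit)[2]),
    p = stats::anova(fit)[["Pr(>F)"]][1])
}

# brute-force group-by variance decomposition for the q-statistic
q_brute_oracle <- function(y, strata) {
  groups <- split(y, strata)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  sst <- sum((y - mean(y))^2)
  1 - ssw / sst
}

# two-step residualization formula for the second-order partial correlation
partial_resid_oracle <- function(y, x, c1, c2) {
  ry <- stats::residuals(stats::lm(y ~ c1 + c2))
  rx <- stats::residuals(stats::lm(x ~ c1 + c2))
  stats::cor(ry, rx)
}

multiple_r2_lm_oracle <- function(y, X) {
  summary(stats::lm(y ~ X))$r.squared
}

# small default scenario used across tests (kept tiny for speed)
tiny_scenario <- function(seed = 11L, ...) {
  nep_scenario(shape = c(12L, 15L), years = 2000:2005, seed = seed, ...)
}
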