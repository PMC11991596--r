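test_that("matrix-inversion partials agree with residualization", {
  set.seed(20)
  for (k in 1:100) {
    n <- sample(10:80, 1)
    m <- matrix(rnorm(n * 4), n, 4)
    m[, 1] <- m[, 1] + 0.5 * m[, 3]           # entangle with a control
    got <- partial_correlation(m[, 1], m[, 2], m[, 3:4])
    expect_equal(got$r, partial_resid_oracle(m[, 1], m[, 2], m[, 3], m[, 4]),
                 tolerance = 1e-10)
  }
})

test_that("partial correlation handles dependence structure correctly", {
  set.seed(21)
  x <- rnorm(50); c1 <- rnorm(50); c2 <- rnorm(50)
  expect_equal(partial_correlation(x, x, cbind(c1, c2))$r, 1)
  # y equal to a control: residual response is (numerically) gone
  res <- partial_correlation(c1, x, cbind(c1, c2))
  expect_true(is.na(res$r) || abs(res$r) < 0.2)
  # near-duplicate of a control with noise: partial against x stays small
  reps <- vapply(1:500, function(s) {
    set.seed(300 + s)
    x <- rnorm(200); c1 <- rnorm(200); c2 <- rnorm(200)
    y <- c1 + rnorm(200, sd = 0.05)
    abs(partial_correlation(y, x, cbind(c1, c2))$r)
  }, numeric(1))
  expect_gte(mean(reps < 0.15), 0.95)
  expect_error(partial_correlation(1:4, 1:4, cbind(1:4, 1:4)), "n >= 5")
})

test_that("prescribed partial correlation is recovered", {
  est <- vapply(1:20, function(s) {
    m <- generate_partial_structure(500, 0.5, seed = s)
    partial_correlation(m[, 1], m[, 2], m[, 3:4])$r
  }, numeric(1))
  expect_gte(mean(abs(est - 0.5) <= 0.1), 0.95)
})

test_that("multiple correlation matches its regression definition", {
  set.seed(22)
  X <- matrix(rnorm(60), 20, 3)
  y <- X[, 1] * 0.7 + rnorm(20)
  got <- multiple_correlation(y, X)
  expect_equal(got$r2, multiple_r2_lm_oracle(y, X), tolerance = 1e-10)
  # exact linear combinations give R = 1
  expect_equal(multiple_correlation(X[, 1], X)$R, 1)
  expect_equal(multiple_correlation(0.5 * X[, 1] + 0.5 * X[, 2], X)$R, 1)
  # affine rescaling of predictors leaves R untouched
  X2 <- sweep(X, 2, c(10, -3, 0.5), `*`)
  expect_equal(multiple_correlation(y, X2)$R, got$R, tolerance = 1e-10)
  # collinear predictors are refused with a reason
  Xc <- cbind(X[, 1], X[, 1], X[, 2])
  expect_true(!is.null(multiple_correlation(y, Xc)$reason))
})

test_that("the nine driving types partition the decision space", {
  # multiple-correlation gate
  expect_equal(classify_driver_type(c(0.001, 0.2, 0.3), 0.2), "non_climatic")
  # single significant partials
  expect_equal(classify_driver_type(c(0.01, 0.5, 0.5), 0.01),
               "temperature_driven")
  expect_equal(classify_driver_type(c(0.5, 0.01, 0.5), 0.01),
               "precipitation_driven")
  expect_equal(classify_driver_type(c(0.5, 0.5, 0.01), 0.01),
               "solar_radiation_driven")
  # pairs
  expect_equal(classify_driver_type(c(0.01, 0.02, 0.5), 0.01),
               "temperature_precipitation_driven")
  expect_equal(classify_driver_type(c(0.01, 0.5, 0.02), 0.01),
               "temperature_solar_driven")
  expect_equal(classify_driver_type(c(0.5, 0.01, 0.02), 0.01),
               "precipitation_solar_driven")
  # all three / none
  expect_equal(classify_driver_type(c(0.001, 0.001, 0.001), 0.001),
               "strongly_driven_by_T_P_S")
  expect_equal(classify_driver_type(c(0.5, 0.5, 0.5), 0.01),
               "weakly_driven_by_T_P_S")
  expect_true(is.na(classify_driver_type(c(NA, 0.5, 0.5), 0.01)))
})

attribution_fixture <- function(mode, nr = 15, nc = 15, ny = 24, seed = 1) {
  set.seed(seed)
  Tann <- array(rnorm(nr * nc * ny), c(nr, nc, ny))
  Pann <- array(rnorm(nr * nc * ny), c(nr, nc, ny))
  Sann <- array(rnorm(nr * nc * ny), c(nr, nc, ny))
  nep <- switch(mode,
    precipitation = 2 * Pann + array(rnorm(nr * nc * ny, sd = 0.2),
                                     c(nr, nc, ny)),
    independent = array(rnorm(nr * nc * ny), c(nr, nc, ny)))
  list(nep = nep, clim = list(T = Tann, R = Pann, SOL = Sann))
}

test_that("a precipitation-controlled response maps to precipitation types", {
  fx <- attribution_fixture("precipitation")
  am <- attribution_map(fx$nep, fx$clim)
  rain_types <- c("precipitation_driven", "temperature_precipitation_driven",
                  "precipitation_solar_driven", "strongly_driven_by_T_P_S")
  expect_gt(sum(am$type_proportions[rain_types]), 0.5)
  expect_equal(sum(am$type_proportions), 1)
  # partial correlation with precipitation is overwhelmingly positive
  expect_gt(am$positive_fraction[["P"]], 0.95)
})

test_that("climate-independent response is typed non-climatic at ~1-alpha", {
  fx <- attribution_fixture("independent", nr = 40, nc = 50)
  am <- attribution_map(fx$nep, fx$clim)
  expect_gt(am$type_proportions[["non_climatic"]], 0.92)
  expect_lt(am$type_proportions[["non_climatic"]], 0.98)
})

test_that("degenerate pixels are dropped, and map values equal the ops", {
  fx <- attribution_fixture("precipitation")
  fx$nep[2, 2, ] <- 42                      # constant series -> dropped
  am <- attribution_map(fx$nep, fx$clim)
  expect_true(is.na(am$type[2, 2]))
  expect_gte(am$n_dropped, 1)
  # spot-check pixels against the scalar operations
  for (px in list(c(1, 1), c(5, 7), c(15, 15))) {
    y <- fx$nep[px[1], px[2], ]
    Tv <- fx$clim$T[px[1], px[2], ]; Pv <- fx$clim$R[px[1], px[2], ]
    Sv <- fx$clim$SOL[px[1], px[2], ]
    pc <- partial_correlation(y, Pv, cbind(Tv, Sv))
    expect_equal(am$r_partial$P[px[1], px[2]], pc$r, tolerance = 1e-10)
    expect_equal(am$p_partial$P[px[1], px[2]], pc$p, tolerance = 1e-10)
    mc <- multiple_correlation(y, cbind(Tv, Pv, Sv))
    expect_equal(am$R_multiple[px[1], px[2]], mc$R, tolerance = 1e-10)
    # OLS-with-intercept property: R^2 >= any single squared correlation
    expect_gte(mc$r2 + 1e-12,
               max(stats::cor(y, Tv)^2, stats::cor(y, Pv)^2,
                   stats::cor(y, Sv)^2))
  }
})
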