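test_that("FPAR is linear in NDVI between the type's bounds and clamped", {
  p <- casa_params()
  veg <- matrix(1L, 1, 3)
  lo <- p$table$ndvi_min[1]; hi <- p$table$ndvi_max[1]
  ndvi <- matrix(c(lo, (lo + hi) / 2, hi), 1, 3)
  fp <- compute_fpar(ndvi, veg, p)
  expect_equal(fp[1, 1], 0)
  expect_equal(fp[1, 2], p$fpar_max / 2)      # midway -> half the cap
  expect_equal(fp[1, 3], p$fpar_max)
  # below bare soil stays 0, above saturation stays capped
  expect_equal(compute_fpar(matrix(-0.2), matrix(1L), p)[1, 1], 0)
  expect_equal(compute_fpar(matrix(0.99), matrix(1L), p)[1, 1], p$fpar_max)
  expect_error(compute_fpar(matrix(1.5), matrix(1L), p), "NDVI")
  expect_error(compute_fpar(matrix(0.5), matrix(9L), p), "known codes")
})

test_that("APAR is the PAR fraction of absorbed solar radiation", {
  p <- casa_params()
  expect_equal(compute_apar(matrix(0), matrix(0.5), p)[1, 1], 0)
  expect_equal(compute_apar(matrix(400), matrix(0.5), p)[1, 1], 100)
  set.seed(1)
  sol <- matrix(runif(50, 0, 600), 5, 10)
  fp <- matrix(runif(50), 5, 10)
  expect_true(all(compute_apar(sol, fp, p) <= 0.5 * sol + 1e-12))
  expect_error(compute_apar(matrix(-1), matrix(0.5), p), "negative")
})

lue_fixture <- function(T_const, R_const, topt = 20, nmonth = 12) {
  ta <- array(T_const, c(2, 2, nmonth))
  ra <- array(R_const, c(2, 2, nmonth))
  veg <- matrix(1L, 2, 2)
  compute_lue(ta, ra, veg, topt = matrix(topt, 2, 2))
}

test_that("light-use efficiency respects its stress-scalar structure", {
  p <- casa_params()
  emax <- p$table$emax[1]
  # optimal temperature, zero precipitation: water stress at its 0.5 floor
  st <- lue_fixture(20, 0)
  expect_true(all(st$w == 0.5))
  expect_true(all(st$lue > 0.49 * emax & st$lue <= 0.5 * emax))
  # saturating precipitation: water stress at 1, lue near emax
  st2 <- lue_fixture(20, 1e4)
  expect_true(all(st2$w == 1))
  expect_true(all(st2$lue <= emax & st2$lue > 0.98 * emax))
  # far below the optimum the temperature stresses collapse
  st3 <- lue_fixture(-10, 100, topt = 20)
  expect_true(all(st3$t1 * st3$t2 < 0.5))
  # scalars always within [0, 1], lue within [0, emax]
  for (st_i in list(st, st2, st3)) {
    expect_true(all(st_i$t1 >= 0 & st_i$t1 <= 1))
    expect_true(all(st_i$t2 >= 0 & st_i$t2 <= 1))
    expect_true(all(st_i$w >= 0.5 & st_i$w <= 1))
    expect_true(all(st_i$lue >= 0 & st_i$lue <= emax))
  }
})

npp_fixture <- function(seed = 11L, mutate = identity) {
  sc <- tiny_scenario(seed = seed)
  cl <- generate_climate(sc)
  veg <- generate_vegetation(sc, cl)
  cl <- mutate(cl)
  list(npp = compute_npp(cl, veg$ndvi, veg$vegtype), climate = cl,
       veg = veg)
}

test_that("NPP obeys its product identity and annual aggregation exactly", {
  fx <- npp_fixture()
  npp <- fx$npp
  expect_equal(npp$npp_monthly, npp$apar * npp$lue, tolerance = 0)
  expect_true(all(npp$npp_monthly >= 0, na.rm = TRUE))
  for (j in seq_along(npp$years)) {
    sel <- which(npp$time_index$year == npp$years[j])
    expect_equal(npp$npp_annual[, , j],
                 apply(npp$npp_monthly[, , sel], c(1, 2), sum),
                 tolerance = 0)
  }
})

test_that("NPP is linear in solar radiation and zero at zero efficiency", {
  fx <- npp_fixture()
  fx2 <- npp_fixture(mutate = function(cl) {
    cl$SOL$values <- cl$SOL$values * 2; cl
  })
  expect_equal(fx2$npp$npp_monthly, fx$npp$npp_monthly * 2, tolerance = 1e-12)
  # a vegetation class with emax = 0 fixes NPP at 0
  p0 <- casa_params(table = data.frame(code = 1:3, ndvi_min = 0.05,
                                       ndvi_max = 0.9, emax = 0))
  npp0 <- compute_npp(fx$climate, fx$veg$ndvi, fx$veg$vegtype, p0)
  expect_true(all(npp0$npp_monthly == 0))
})

test_that("raising NDVI never lowers NPP", {
  fx <- npp_fixture()
  ndvi2 <- fx$veg$ndvi
  ndvi2$values <- pmin(ndvi2$values + 0.05, 1)
  npp2 <- compute_npp(fx$climate, ndvi2, fx$veg$vegtype)
  expect_true(all(npp2$npp_monthly - fx$npp$npp_monthly >= -1e-12))
})

test_that("NPP validation behaves like a seeded Pearson correlation", {
  set.seed(7)
  est <- matrix(runif(400, 300, 900), 20, 20)
  v <- validate_npp(est, est, n_points = 100, seed = 1)
  expect_equal(v$r, 1); expect_equal(v$r2, 1)
  v2 <- validate_npp(est, 2 * est + 5, n_points = 100, seed = 1)
  expect_equal(v2$r, 1, tolerance = 1e-12)
  expect_identical(validate_npp(est, est + 1, seed = 3)$r,
                   validate_npp(est, est + 1, seed = 3)$r)
  expect_error(validate_npp(est[1:5, 1:5], est[1:5, 1:5], n_points = 100),
               "valid common pixels")
  # unrelated reference: correlation stays small across seeds
  ok <- vapply(1:20, function(s) {
    set.seed(s + 100)
    ref <- matrix(runif(400, 300, 900), 20, 20)
    abs(validate_npp(est, ref, n_points = 100, seed = s)$r) < 0.3
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
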