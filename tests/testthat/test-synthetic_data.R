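test_that("identical scenario and seed reproduce bit-identical layers", {
  sc <- tiny_scenario(seed = 5L)
  a <- generate_climate(sc); b <- generate_climate(sc)
  expect_identical(a$T$values, b$T$values)
  expect_identical(a$R$values, b$R$values)
  va <- generate_vegetation(sc, a); vb <- generate_vegetation(sc, b)
  expect_identical(va$ndvi$values, vb$ndvi$values)
  da <- generate_drivers(sc); db <- generate_drivers(sc)
  expect_identical(da$response$values, db$response$values)
  # a different seed changes the fields
  expect_false(identical(
    generate_climate(tiny_scenario(seed = 6L))$T$values, a$T$values))
})

test_that("noise-free, trend-free climate repeats the same annual cycle", {
  sc <- tiny_scenario()
  for (v in names(sc$climate_params)) {
    sc$climate_params[[v]]$sd <- 0
    sc$climate_params[[v]]$trend <- 0
  }
  cl <- generate_climate(sc)
  y1 <- cl$T$values[, , 1:12]
  for (y in 2:length(sc$years))
    expect_equal(cl$T$values[, , (y - 1) * 12 + 1:12], y1)
})

test_that("a configured warming trend appears exactly in annual means", {
  sc <- tiny_scenario()
  sc$climate_params$T$sd <- 0
  sc$climate_params$T$trend <- 0.1
  cl <- generate_climate(sc)
  ann <- vapply(seq_along(sc$years), function(y)
    mean(cl$T$values[, , (y - 1) * 12 + 1:12]), numeric(1))
  expect_equal(diff(ann), rep(0.1, length(sc$years) - 1), tolerance = 1e-12)
})

test_that("mean annual precipitation matches its configured level (CLT)", {
  sc <- nep_scenario(shape = c(10L, 20L), years = 2000L, seed = 99L)
  sc$climate_params$R <- list(mean = 120, amp = 80, grad = 0, sd = 5,
                              trend = 0)
  cl <- generate_climate(sc)
  annual <- apply(cl$R$values, c(1, 2), sum)
  level <- 120 + 80 * cos(2 * pi * ((1:12) - 6) / 12)
  se <- sqrt(sum((5 * level / 120)^2) / 200)
  expect_lt(abs(mean(annual) - 12 * 120), 3 * se)
})

test_that("NDVI decoupled from climate equals its baseline, and clips", {
  sc <- tiny_scenario()
  sc$ndvi_params <- list(baseline = 0.4, relief = 0, a = 0, b = 0, sd = 0)
  cl <- generate_climate(sc)
  # an all-constant NDVI field is flagged as degenerate for correlations
  expect_warning(veg <- generate_vegetation(sc, cl), "constant")
  expect_true(all(veg$ndvi$values == 0.4))
  sc$ndvi_params$baseline <- 1.5
  veg2 <- suppressWarnings(generate_vegetation(sc, cl))
  expect_true(all(veg2$ndvi$values == 1.0))
  expect_gte(length(unique(as.vector(veg$vegtype$values))), 2)
})

test_that("temperature-coupled NDVI correlates positively with temperature", {
  sc <- nep_scenario(shape = c(10L, 10L), years = 2000:2023, seed = 4L)
  sc$ndvi_params <- list(baseline = 0.5, relief = 0.1, a = 0.3, b = 0,
                         sd = 0.02)
  cl <- generate_climate(sc)
  veg <- generate_vegetation(sc, cl)
  cors <- vapply(seq_len(100), function(px) {
    i <- (px - 1) %% 10 + 1; j <- (px - 1) %/% 10 + 1
    stats::cor(veg$ndvi$values[i, j, ], cl$T$values[i, j, ])
  }, numeric(1))
  expect_gte(mean(cors > 0), 0.95)
})

test_that("driver layers carry the standard class counts and full truth", {
  sc <- tiny_scenario()
  drv <- generate_drivers(sc)
  L <- vapply(c("impervious_change", "human_footprint_change",
                "land_use_change", "arable_expansion_change"),
              function(nm) length(unique(as.vector(drv$drivers[[nm]]$values))),
              numeric(1))
  expect_equal(unname(L), c(3, 6, 12, 4))
  expect_setequal(names(drv$truth$effects), names(sc$driver_params))
  expect_equal(drv$truth$stratum_means$impervious_change,
               sc$response_params$baseline +
                 sc$driver_params$impervious_change$effects)
})

test_that("a null driver design yields near-zero explanatory power", {
  dp <- default_driver_params()
  for (nm in names(dp)) {
    if (dp[[nm]]$type == "categorical")
      dp[[nm]]$effects <- rep(0, dp[[nm]]$L)
    else dp[[nm]]$beta <- 0
  }
  sc <- nep_scenario(shape = c(50L, 50L), years = 2000L, seed = 8L,
                     driver_params = dp,
                     response_params = list(baseline = 380, noise_sd = 10))
  drv <- generate_drivers(sc)
  y <- as.vector(drv$response$values)
  for (nm in c("impervious_change", "land_use_change")) {
    q <- factor_q(y, as.vector(drv$drivers[[nm]]$values))$q
    expect_lt(q, 0.05)
  }
})

test_that("prescribed-partial-correlation samples are reproducible and sized", {
  m <- generate_partial_structure(100, 0.5, seed = 3L)
  expect_equal(dim(m), c(100L, 4L))
  expect_identical(m, generate_partial_structure(100, 0.5, seed = 3L))
  expect_error(generate_partial_structure(10, 1.2), "abs")
})

test_that("injected-trend stacks record their truth", {
  g <- generate_trend_stack(c(5, 5), 2000:2009, slope = 3, noise_sd = 0,
                            seed = 2L)
  expect_equal(g$truth$slope, 3)
  series <- g$nep$values[2, 3, ]
  expect_equal(diff(series), rep(3, 9), tolerance = 1e-12)
})
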