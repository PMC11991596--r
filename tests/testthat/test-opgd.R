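test_that("break schemes cut as defined", {
  eq <- discretize(1:10, "equal", 2)
  expect_equal(as.vector(table(eq$strata)), c(5, 5))
  expect_equal(eq$breaks[2], 5.5)
  qu <- discretize(1:10, "quantile", 5)
  expect_equal(as.vector(table(qu$strata)), rep(2, 5))
  # bimodal data: natural breaks separate the modes perfectly
  x <- c(rep(0, 50) + rnorm(50, sd = 0.1), rep(100, 50) + rnorm(50, sd = 0.1))
  nb <- discretize(x, "natural_breaks", 2)
  expect_equal(length(unique(nb$strata[1:50])), 1)
  expect_equal(length(unique(nb$strata[51:100])), 1)
  expect_false(nb$strata[1] == nb$strata[51])
  for (m in c("geometric", "std_dev")) {
    fl <- discretize(stats::runif(200, -5, 40), m, 6)
    expect_true(all(diff(fl$breaks) > 0))
    expect_false(anyNA(fl$strata))
    expect_equal(fl$L, 6L)
  }
  expect_error(discretize(rep(1:3, 10), "equal", 5, name = "elev"), "elev")
})

test_that("q-statistic reproduces hand-computed variance decompositions", {
  expect_equal(factor_q(c(1, 1, 2, 2), c(1, 1, 2, 2))$q, 1)
  expect_equal(factor_q(c(1, 2, 1, 2), c(1, 1, 2, 2))$q, 0)
  # SSW = 1, SST = 5 -> q = 0.8
  expect_equal(factor_q(c(0, 1, 2, 3), c(1, 1, 2, 2))$q, 0.8)
  expect_true(is.na(factor_q(rep(3, 6), rep(1:2, 3))$q))
  expect_error(factor_q(1:5, rep(1, 5)), "2 non-empty strata")
})

test_that("q matches the brute-force group-by oracle", {
  set.seed(30)
  for (k in 1:100) {
    n <- sample(20:150, 1)
    L <- sample(2:6, 1)
    s <- sample(L, n, replace = TRUE)
    y <- rnorm(n) + s * runif(1, 0, 2)
    expect_equal(factor_q(y, s)$q, q_brute_oracle(y, s), tolerance = 1e-12)
  }
})

test_that("q is invariant to relabeling and location-scale, monotone under refinement", {
  set.seed(31)
  y <- rnorm(200); s <- sample(4, 200, replace = TRUE)
  q0 <- factor_q(y, s)$q
  expect_equal(factor_q(y, 5 - s)$q, q0, tolerance = 1e-14)
  expect_equal(factor_q(3 * y - 7, s)$q, q0, tolerance = 1e-12)
  # splitting a stratum never lowers q
  s2 <- s
  split_me <- which(s == 2)
  s2[split_me[seq_len(length(split_me) %/% 2)]] <- 5L
  expect_gte(factor_q(y, s2)$q, q0 - 1e-12)
})

test_that("q significance: noncentral-F and permutation tests concur", {
  s <- rep(1:3, each = 40)
  # strong stratified effects are always detected by both tests
  for (sd_ in 1:5) {
    set.seed(600 + sd_)
    y_eff <- rnorm(120) + c(0, 1.2, 2.4)[s]
    expect_lt(factor_q(y_eff, s)$p, 0.01)
    expect_lt(permutation_q_test(y_eff, s, n_perm = 199, seed = 1)$p, 0.01)
  }
  # under the null both tests reject rarely, and they agree on the call
  calls <- t(vapply(1:20, function(sd_) {
    set.seed(700 + sd_)
    y0 <- rnorm(120)
    c(ncf = factor_q(y0, s)$p < 0.05,
      perm = permutation_q_test(y0, s, n_perm = 199, seed = 1)$p < 0.05)
  }, logical(2)))
  expect_lte(sum(calls[, "ncf"]), 3)
  expect_lte(sum(calls[, "perm"]), 3)
  expect_gte(mean(calls[, "ncf"] == calls[, "perm"]), 0.9)
})

test_that("discretization search maximizes q with the stated tie-breaks", {
  x <- rep(1:300, 1)
  y <- c(rep(10, 100), rep(20, 100), rep(30, 100))
  opt <- optimize_discretization(x, y, L_range = 3:6)
  expect_equal(opt$q_result$q, 1)
  expect_equal(opt$factor$L, 3L)            # ties resolve to the smallest L
  expect_true(all(c("method", "L", "q") %in% names(opt$search)))
  # independent response: optimal q stays small
  set.seed(33)
  qs <- vapply(1:5, function(s) {
    set.seed(400 + s)
    optimize_discretization(runif(1000), rnorm(1000))$q_result$q
  }, numeric(1))
  expect_true(all(qs < 0.1))
  expect_error(optimize_discretization(rep(1, 50), rnorm(50), name = "flat"),
               "flat")
})

test_that("interaction rules label constructed q triples", {
  expect_equal(classify_interaction(0.3, 0.4, 0.9), "nonlinear_enhancement")
  expect_equal(classify_interaction(0.3, 0.4, 0.6), "linear_enhancement")
  expect_equal(classify_interaction(0.3, 0.4, 0.7), "independence")
  expect_equal(classify_interaction(0.3, 0.4, 0.35), "linear_weakening")
  expect_equal(classify_interaction(0.3, 0.4, 0.2), "nonlinear_weakening")
})

test_that("interaction detector recognizes engineered regimes", {
  # xor design: neither factor explains alone, together they are exact
  f1 <- rep(c(1, 1, 2, 2), 25); f2 <- rep(c(1, 2, 1, 2), 25)
  y_xor <- as.numeric(xor(f1 == 2, f2 == 2))
  it <- interaction_detect(y_xor, f1, f2)
  expect_equal(it$type, "nonlinear_enhancement")
  expect_equal(it$q12, 1)
  # additive balanced orthogonal design: q12 = q1 + q2 (independence)
  y_add <- c(0, 10)[f1] + c(0, 4)[f2]
  expect_equal(interaction_detect(y_add, f1, f2)$type, "independence")
  # noisy copy factor: enhancement without exceeding additivity
  set.seed(34)
  g <- sample(3, 300, replace = TRUE)
  y <- c(0, 5, 10)[g] + rnorm(300, sd = 2)
  g2 <- ifelse(runif(300) < 0.3, sample(3, 300, replace = TRUE), g)
  it2 <- interaction_detect(y, g, g2)
  expect_equal(it2$type, "linear_enhancement")
  # without merging the cross-classification refines both factors
  set.seed(35)
  for (k in 1:20) {
    s1 <- sample(3, 80, TRUE); s2 <- sample(4, 80, TRUE)
    yy <- rnorm(80) + s1
    itk <- interaction_detect(yy, s1, s2, min_stratum_size = 1)
    expect_gte(itk$q12, max(itk$q1, itk$q2) - 1e-12)
  }
})

test_that("forced stratum merging can produce both weakening regimes", {
  set.seed(36)
  y <- c(rnorm(50, 0), rnorm(50, 10))
  f1 <- rep(1:2, each = 50)
  f2 <- sample(rep(1:25, 4))
  it <- interaction_detect(y, f1, f2, min_stratum_size = 40)
  expect_equal(it$type, "linear_weakening")
  expect_gt(it$n_merged, 0)
  yu <- seq(0, 10, length.out = 100) + rnorm(100, sd = 0.1)
  g1 <- as.integer(cut(yu, 10)); g2 <- as.integer(cut(yu + 0.5, 10))
  it2 <- interaction_detect(yu, g1, g2, min_stratum_size = 100)
  expect_equal(it2$type, "nonlinear_weakening")
})

test_that("risk detector finds the optimal stratum and controls the null", {
  set.seed(37)
  s <- rep(1:3, each = 50)
  y <- c(100, 300, 500)[s] + rnorm(150, sd = 10)
  rk <- risk_detect(y, s, labels = c("low", "mid", "high"))
  expect_equal(rk$optimal_label, "high")
  expect_equal(rk$minimal_label, "low")
  expect_true(all(rk$pairwise_significant[upper.tri(rk$pairwise_significant)]))
  expect_equal(unname(rk$stratum_means["high"]), 500, tolerance = 5)
  # one common distribution: pairwise differences rarely significant
  # (alpha shared across the three pair tests)
  clean <- vapply(1:30, function(sd_) {
    set.seed(500 + sd_)
    yn <- rnorm(150)
    rkn <- risk_detect(yn, s, alpha = 0.05 / 3)
    !any(rkn$pairwise_significant)
  }, logical(1))
  expect_gte(mean(clean), 0.9)
  # singleton strata keep their mean but skip the t-tests
  rk1 <- risk_detect(c(1, 2, 3, 100), c(1, 1, 1, 2))
  expect_equal(unname(rk1$stratum_means[2]), 100)
  expect_true(all(is.na(rk1$pairwise_p[1, 2])))
})

test_that("stratum means recover generator truth", {
  sc <- nep_scenario(
    shape = c(40L, 40L), years = 2000L, seed = 50L,
    driver_params = list(test = list(type = "categorical", L = 3L,
                                     effects = c(-200, 0, 200))),
    response_params = list(baseline = 300, noise_sd = 10))
  drv <- generate_drivers(sc)
  rk <- risk_detect(as.vector(drv$response$values),
                    as.vector(drv$drivers$test$values))
  truth <- drv$truth$stratum_means$test
  expect_true(all(abs(rk$stratum_means - truth) <= 2 * 10))
  expect_equal(unname(rk$optimal_stratum), which.max(truth))
})
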