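# brute-force rank oracle: average ranks, then the explicit Pearson formula
pearson_manual <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

test_that("spearman correlation handles monotone, reversed and tied data", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_rho(1:3, c(30, 20, 10)), -1)
  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  expect_equal(spearman_rho(x, y), pearson_manual(rank(x), rank(y)))
  expect_true(is.na(spearman_rho(c(1, 1, 1), 1:3)))
  expect_error(spearman_rho(1:2, 1:2), class = "dwburden_usage_error")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(30); y <- rnorm(30)
    base <- spearman_rho(x, y)
    expect_equal(spearman_rho(exp(x), y), base)
    expect_equal(spearman_rho(x, y^3 + 5 * y), base)
  }
})

test_that("MC sensitivity recovers the monotone chain structure", {
  # single chemical, fixed removal: burden strictly increasing in CS
  cecs <- point_cecs(conc = 100, ef_ca = 1, ef_nc = 1, category = "DBP")
  cecs$conc_low <- 50; cecs$conc_high <- 150
  tr <- point_train(cecs$cec_id, 0.5)
  run <- run_mc(cecs, list(t = tr), n_iter = 500, seed = 2)
  sens <- mc_sensitivity(run$t, "cancer")
  expect_equal(sens$rho[sens$parameter == "cs:p01"], 1)

  # with removal uncertainty: concentration pulls up, removal pulls down
  tr2 <- tr
  tr2$units$u1$removal$r_low <- 0.3
  tr2$units$u1$removal$r_high <- 0.7
  run2 <- run_mc(cecs, list(t = tr2), n_iter = 500, seed = 2)
  sens2 <- mc_sensitivity(run2$t, "cancer")
  expect_gt(sens2$rho[sens2$parameter == "cs:p01"], 0.5)
  expect_lt(sens2$rho[sens2$parameter == "removal:u1:p01"], 0)
})

test_that("parameters not entering an endpoint show null correlations", {
  cecs <- point_cecs(conc = c(100, 80), ef_ca = c(1, NA), ef_nc = c(1, 1),
                     category = c("DBP", "PCP"))
  cecs$conc_low <- cecs$conc_mode * 0.5
  cecs$conc_high <- cecs$conc_mode * 1.5
  n <- 2000
  run <- run_mc(cecs, list(source = NULL), n_iter = n, seed = 3)
  sens <- mc_sensitivity(run$source, "cancer")
  rho_null <- sens$rho[sens$parameter == "cs:p02"]
  expect_lt(abs(rho_null), 3 / sqrt(n))
})

test_that("sensitivity requires recorded draws", {
  cecs <- point_cecs()
  run <- run_mc(cecs, list(source = NULL), n_iter = 20, seed = 1,
                keep_draws = FALSE)
  expect_error(mc_sensitivity(run$source), class = "dwburden_usage_error")
})

test_that("OAT coefficients reproduce the secant arithmetic", {
  lin <- oat_sensitivity(function(x) 2 * x, base = 5)
  expect_equal(lin$sc_plus, 1)
  expect_equal(lin$sc_minus, 1)
  expect_equal(lin$sc_mean, 1)

  const <- oat_sensitivity(function(x) 42, base = 5)
  expect_equal(const$sc_mean, 0)

  quad <- oat_sensitivity(function(x) x^2, base = 10)
  expect_equal(quad$sc_plus, 2.2)
  expect_equal(quad$sc_minus, 1.8)
  expect_equal(quad$sc_mean, 2.0)

  zero <- oat_sensitivity(function(x) 0 * x, base = 1)
  expect_true(is.na(zero$sc_mean))
})

test_that("power-law OAT mean elasticity converges to the exponent", {
  for (k in c(0.5, 2, 3.7)) {
    got <- oat_sensitivity(function(x) x^k, base = 2, delta = 1e-4)
    expect_lt(abs(got$sc_mean - k), 1e-6)
  }
})

test_that("oat_sweep perturbs one named parameter at a time", {
  model <- function(p) c(main = p[["a"]]^2 * p[["b"]], side = p[["b"]])
  got <- oat_sweep(model, c(a = 2, b = 3))
  main_a <- got[got$parameter == "a" & got$output == "main", ]
  expect_equal(main_a$sc_mean, 2.0)
  side_a <- got[got$parameter == "a" & got$output == "side", ]
  expect_equal(side_a$sc_mean, 0)
  main_b <- got[got$parameter == "b" & got$output == "main", ]
  expect_equal(main_b$sc_mean, 1.0)
})
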