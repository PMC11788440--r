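test_that("residual concentration follows the multiplicative removal chain", {
  expect_equal(residual_concentration(50, numeric(0)), 50)
  expect_equal(residual_concentration(100, 1.0), 0)
  expect_equal(residual_concentration(100, c(0.5, 0.8)), 10)
  expect_error(residual_concentration(100, c(0.5, 1.2)),
               regexp = "unit index 2", class = "dwburden_domain_error")
  expect_error(residual_concentration(-1, 0.5), class = "dwburden_domain_error")
})

test_that("residual concentration is permutation-invariant and monotone", {
  set.seed(1)
  for (i in 1:25) {
    cs <- runif(1, 0, 1000)
    r <- runif(sample(2:7, 1))
    expect_equal(residual_concentration(cs, r),
                 residual_concentration(cs, rev(r)))
    expect_lte(residual_concentration(cs, r), cs)
    # increasing any removal cannot increase the residual
    r2 <- r
    j <- sample(length(r), 1)
    r2[j] <- min(1, r2[j] + runif(1, 0, 1 - r2[j]))
    expect_lte(residual_concentration(cs, r2), residual_concentration(cs, r))
  }
})

test_that("cumulative intake and ingested mass follow the stated arithmetic", {
  expect_equal(cumulative_intake(exposure_context()), 12775)
  expect_equal(cumulative_intake(exposure_context(ir_daily = 1, years = 1)), 365)
  expect_error(exposure_context(ir_daily = 0), class = "dwburden_domain_error")

  expect_equal(ingested_mass(500000, 12775, 0), 0)
  expect_equal(ingested_mass(500000, 12775, 1), 6.3875e-3)
  expect_equal(ingested_mass(1, 1, 1e12), 1) # ng/L -> kg unit identity
  expect_error(ingested_mass(1, 1, -1), class = "dwburden_domain_error")
})

test_that("health effect and annualization compose to the documented chain", {
  expect_equal(health_effect(11.9, 11.5, 0), 0)
  expect_equal(health_effect(11.9, 11.5, 1e-6), 1.36850e-4, tolerance = 1e-12)
  expect_equal(health_effect(1, 1, 1), 1)

  ctx <- exposure_context()
  expect_equal(annual_per_person(0, ctx), 0)
  expect_equal(annual_per_person(12.5, ctx), 1.0e-6)

  # full chain with point inputs: a high-toxicity chemical at 4.6 ng/L
  ce <- 4.6
  he <- health_effect(11.9, ctx$df_cancer,
                      ingested_mass(ctx$sp, cumulative_intake(ctx), ce))
  expect_equal(annual_per_person(he, ctx),
               oracle_burden(11.9, 11.5, 4.6, numeric(0)),
               tolerance = 1e-12)
  expect_equal(annual_per_person(he, ctx), 3.2168e-7, tolerance = 1e-4)
})

test_that("mixture aggregation honours the three conventions", {
  ctx <- exposure_context()
  expect_equal(aggregate_mixture(c(2e-7, 3e-7), "additive"), 5e-7)
  expect_equal(aggregate_mixture(c(2e-7, 3e-7), "dominant"), 3e-7)
  expect_error(aggregate_mixture(c(1e-7), "nonsense"))
  expect_error(
    aggregate_mixture(1e-7, "multiplicative", per_cec_case_prob = 1.0,
                      ctx = ctx),
    class = "dwburden_domain_error"
  )
  expect_error(aggregate_mixture(1e-7, "multiplicative"),
               class = "dwburden_usage_error")

  # small risks: multiplicative converges to additive from below
  p <- c(2e-5, 5e-5, 1e-5)
  burdens <- ctx$df_cancer * p / ctx$years
  add <- aggregate_mixture(burdens, "additive")
  mult <- aggregate_mixture(burdens, "multiplicative",
                            per_cec_case_prob = p, ctx = ctx,
                            endpoint = "cancer")
  expect_lt(abs(add - mult) / add, 0.001)
  expect_lte(mult, add)
})

test_that("burden table matches the composition oracle at point inputs", {
  cecs <- point_cecs(conc = 4.6, ef_ca = 11.9, ef_nc = 0.5, category = "DBP")
  ctx <- exposure_context()
  bt <- burden_table(cecs, train = NULL, ctx = ctx)
  got_ca <- bt$totals$annual_per_person[bt$totals$endpoint == "cancer"]
  expect_equal(got_ca, oracle_burden(11.9, 11.5, 4.6, numeric(0)),
               tolerance = 1e-12)

  tr <- point_train(cecs$cec_id, c(0.5, 0.8))
  bt2 <- burden_table(cecs, train = tr, ctx = ctx)
  expect_equal(bt2$totals$annual_per_person[bt2$totals$endpoint == "noncancer"],
               oracle_burden(0.5, 2.7, 4.6, c(0.5, 0.8)),
               tolerance = 1e-12)
})

test_that("missing effect factors exclude a chemical per endpoint only", {
  cecs <- point_cecs()
  cecs$ef_cancer[2] <- NA
  bt <- burden_table(cecs)
  per <- bt$per_cec
  expect_equal(sum(per$endpoint == "cancer"), 1)
  expect_equal(sum(per$endpoint == "noncancer"), 2)
  # category totals partition the additive grand total
  for (ep in c("cancer", "noncancer")) {
    expect_equal(
      sum(bt$per_category$annual_per_person[bt$per_category$endpoint == ep]),
      bt$totals$annual_per_person[bt$totals$endpoint == ep]
    )
  }
})

test_that("additive burden totals are linear in every concentration", {
  cecs <- point_cecs()
  bt <- burden_table(cecs)
  scaled <- cecs
  for (col in c("conc_low", "conc_mode", "conc_high")) {
    scaled[[col]] <- scaled[[col]] * 3.7
  }
  bt2 <- burden_table(scaled)
  expect_equal(bt2$totals$annual_per_person, 3.7 * bt$totals$annual_per_person)
})

test_that("burden table rejects empty input", {
  expect_error(burden_table(tibble::tibble()), class = "dwburden_usage_error")
})
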