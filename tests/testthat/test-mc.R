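test_that("degenerate Monte Carlo equals the deterministic point chain", {
  cecs <- point_cecs()
  tr <- point_train(cecs$cec_id, c(0.5, 0.8))
  run <- run_mc(cecs, list(pt = tr), n_iter = 50, seed = 1)
  bt <- burden_table(cecs, tr)
  for (ep in c("cancer", "noncancer")) {
    expect_equal(length(unique(run$pt$totals[[ep]])), 1)
    expect_equal(run$pt$totals[[ep]][1],
                 bt$totals$annual_per_person[bt$totals$endpoint == ep],
                 tolerance = 1e-12)
  }
})

test_that("runs are bit-identical under the same seed", {
  ds <- generate_cec_dataset(synth_config(
    seed = 8, category_counts = c(pesticide = 5, DBP = 3)
  ))
  a <- run_mc(ds$cecs, ds$trains, n_iter = 100, seed = 99)
  b <- run_mc(ds$cecs, ds$trains, n_iter = 100, seed = 99)
  expect_identical(a$rbf_ro$totals, b$rbf_ro$totals)
  d <- run_mc(ds$cecs, ds$trains, n_iter = 100, seed = 100)
  expect_false(identical(a$rbf_ro$totals, d$rbf_ro$totals))
})

test_that("source-water draws are shared across trains within an iteration", {
  ds <- generate_cec_dataset(synth_config(
    seed = 8, category_counts = c(pesticide = 4, DBP = 2)
  ))
  run <- run_mc(ds$cecs, c(list(source = NULL), ds$trains),
                n_iter = 50, seed = 7)
  expect_identical(run$source$draws$cs, run$rbf_ro$draws$cs)
  expect_identical(run$rbf_ro$draws$cs, run$rbf_et$draws$cs)
})

test_that("empirical CPDF is the rank/n step function", {
  got <- cpdf(c(2, 1, 3))
  expect_equal(got$value, c(1, 2, 3))
  expect_equal(got$prob, c(1, 2, 3) / 3)
  const <- cpdf(rep(4, 5))
  expect_equal(const$value, rep(4, 5))
  expect_equal(max(const$prob), 1)
  expect_error(cpdf(numeric(0)), class = "dwburden_usage_error")
})

test_that("compliance is the inclusive fraction at the threshold", {
  cecs <- point_cecs(conc = 10, ef_ca = 0.5, ef_nc = 0.5, category = "DBP")
  run <- run_mc(cecs, list(source = NULL), n_iter = 40, seed = 1)
  mc <- run$source
  expect_equal(compliance_fraction(mc, "cancer", threshold = Inf), 100)
  expect_equal(compliance_fraction(mc, "cancer", threshold = 0), 0)
  # inclusive at exactly the sample value
  v <- mc$totals$cancer[1]
  expect_equal(compliance_fraction(mc, "cancer", threshold = v), 100)
  # definitional consistency with the CPDF
  cp <- cpdf(mc, "cancer")
  thr <- v
  expect_equal(max(cp$prob[cp$value <= thr]),
               compliance_fraction(mc, "cancer", thr) / 100)
  # monotone in the threshold
  ths <- sort(runif(10, 0, 2 * v))
  comps <- vapply(ths, function(t) compliance_fraction(mc, "cancer", t),
                  numeric(1))
  expect_true(all(diff(comps) >= 0))
})

test_that("paired benefit counts strictly improving iterations", {
  bm <- generate_two_system_benchmark(seed = 2, n_cec = 6)
  run <- run_mc(bm$cecs, bm$trains, ctx = bm$ctx, n_iter = 300, seed = 21)
  pb <- paired_benefit(run$conventional, run$membrane, "noncancer")
  expect_equal(pb$benefit_percent, 100)
  expect_true(all(pb$differences < 0))

  # a constant positive shift can never look beneficial
  shifted <- run$conventional
  shifted$totals$noncancer <- run$conventional$totals$noncancer + 1e-9
  pb2 <- paired_benefit(run$conventional, shifted, "noncancer")
  expect_equal(pb2$benefit_percent, 0)

  short <- run_mc(bm$cecs, bm$trains["membrane"], ctx = bm$ctx,
                  n_iter = 100, seed = 21)
  expect_error(paired_benefit(run$conventional, short$membrane, "cancer"),
               class = "dwburden_usage_error")
})

test_that("summary quantiles follow type-7 interpolation", {
  mc <- structure(list(label = "x", n_iter = 100, seed = 1,
                       ctx = exposure_context(), mixture_mode = "additive",
                       totals = list(cancer = as.numeric(1:100),
                                     noncancer = rep(2, 100)),
                       per_category = list(), per_cec = list()),
                  class = "mc_result")
  s <- mc_summary(mc)
  ca <- s[s$endpoint == "cancer", ]
  expect_equal(ca$median, 50.5)
  expect_equal(ca$p5, 5.95)
  expect_equal(ca$p95, 95.05)
  nc <- s[s$endpoint == "noncancer", ]
  expect_true(all(unlist(nc[c("median", "p5", "p95", "mean")]) == 2))

  # equivariance under scaling
  mc2 <- mc
  mc2$totals$cancer <- mc$totals$cancer * 3
  s2 <- mc_summary(mc2)
  expect_equal(s2$median[1], 3 * ca$median)
  expect_equal(s2$ci_hi[1], 3 * ca$ci_hi)
})

test_that("convergence check compares seeds and flags identical ones", {
  cecs <- point_cecs()
  r1 <- run_mc(cecs, list(source = NULL), n_iter = 30, seed = 1)$source
  r2 <- run_mc(cecs, list(source = NULL), n_iter = 30, seed = 2)$source
  cc <- convergence_check(r1, r2)
  expect_equal(cc$max_rel_dev, 0) # point inputs: no sampling variability
  expect_true(cc$pass)
  expect_error(convergence_check(r1, r1), class = "dwburden_usage_error")
})

test_that("more iterations tighten repeat-run agreement", {
  bm <- generate_two_system_benchmark(seed = 6, n_cec = 5)
  dev_at <- function(n) {
    r1 <- run_mc(bm$cecs, bm$trains["membrane"], ctx = bm$ctx,
                 n_iter = n, seed = 301)$membrane
    r2 <- run_mc(bm$cecs, bm$trains["membrane"], ctx = bm$ctx,
                 n_iter = n, seed = 302)$membrane
    convergence_check(r1, r2)$max_rel_dev
  }
  expect_lt(dev_at(4000), dev_at(10))
})
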