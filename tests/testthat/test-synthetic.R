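test_that("default synthetic dataset reproduces the study composition", {
  ds <- generate_cec_dataset(synth_config(seed = 1))
  expect_equal(nrow(ds$cecs), 93)
  counts <- table(ds$cecs$category)
  expect_equal(counts[["pesticide"]], 41)
  expect_equal(counts[["industrial"]], 19)
  expect_equal(counts[["pharmaceutical"]], 17)
  expect_equal(counts[["antibiotic"]], 7)
  expect_equal(counts[["DBP"]], 5)
  expect_equal(counts[["PCP"]], 4)
  expect_equal(n_units(ds$trains$rbf_ro), 6)
  expect_equal(n_units(ds$trains$rbf_et), 7)
})

test_that("the generator is deterministic in its seed", {
  a <- generate_cec_dataset(synth_config(seed = 42))
  b <- generate_cec_dataset(synth_config(seed = 42))
  expect_identical(a$cecs, b$cecs)
  expect_identical(a$removals, b$removals)
  c_ <- generate_cec_dataset(synth_config(seed = 43))
  expect_false(identical(a$cecs$conc_mode, c_$cecs$conc_mode))
})

test_that("generator output satisfies loader invariants unmodified", {
  ds <- generate_cec_dataset(synth_config(seed = 5))
  dir <- withr::local_tempdir()
  write_cec_table(ds$cecs_raw, file.path(dir, "cec.csv"))
  write_removal_table(ds$removals, file.path(dir, "rem.csv"))
  cecs <- read_cec_table(file.path(dir, "cec.csv"))
  rem <- read_removal_table(file.path(dir, "rem.csv"))
  tr <- assemble_train(ds$train_defs$rbf_ro, rem, cecs)
  expect_s3_class(tr, "treatment_train")
  expect_equal(n_units(tr), 6)
})

test_that("missing-removal deletion count behaves binomially", {
  cfg <- synth_config(seed = 9, missing_removal_frac = 0.1)
  ds <- generate_cec_dataset(cfg)
  n_total <- 93 * (6 + 7)
  n_missing <- n_total - nrow(ds$removals)
  expected <- n_total * 0.1
  sigma <- sqrt(n_total * 0.1 * 0.9)
  # donor-preservation can retain a few flagged rows, so only the upper
  # bound is exact; the lower bound allows for that slack
  expect_lt(n_missing, expected + 3 * sigma)
  expect_gt(n_missing, expected - 3 * sigma - 5)
  # every deleted entry is reconstructed by imputation in the trains
  for (tr in ds$trains) {
    for (u in tr$units) expect_equal(nrow(u$removal), 93)
  }
})

test_that("censored fraction converges to its configured rate over seeds", {
  frac <- 0.2
  hits <- 0; n <- 0
  for (s in 1:8) {
    ds <- generate_cec_dataset(synth_config(seed = 200 + s, censored_frac = frac))
    hits <- hits + sum(ds$cecs$censored)
    n <- n + nrow(ds$cecs)
  }
  sigma <- sqrt(n * frac * (1 - frac))
  expect_lt(abs(hits - n * frac), 3 * sigma)
})

test_that("DBP effect factors are biased toward the high-toxicity tail", {
  ds <- generate_cec_dataset(synth_config(seed = 31))
  med_dbp <- median(ds$cecs$ef_noncancer[ds$cecs$category == "DBP"])
  med_rest <- median(ds$cecs$ef_noncancer[ds$cecs$category != "DBP"])
  expect_gt(med_dbp, med_rest)
})

test_that("benchmark plants strict dominance and accurate expectations", {
  bm <- generate_two_system_benchmark(seed = 3)
  run <- run_mc(bm$cecs, bm$trains, ctx = bm$ctx, n_iter = 400, seed = 17)
  pb <- paired_benefit(run$conventional, run$membrane, "cancer")
  expect_equal(pb$benefit_percent, 100)
  # identical trains give no strict improvement
  same <- run_mc(bm$cecs, list(a = bm$trains$membrane, b = bm$trains$membrane),
                 ctx = bm$ctx, n_iter = 200, seed = 4)
  # independent removal streams differ per train, so compare a train to itself
  self <- paired_benefit(same$a, same$a, "cancer")
  expect_equal(self$benefit_percent, 0)
})

test_that("lci fixture shares sum to one with planted mix ordering", {
  fx <- generate_lci_fixture(seed = 1)
  sums <- fx$mixes |>
    dplyr::group_by(country_id) |>
    dplyr::summarise(s = sum(share))
  expect_true(all(abs(sums$s - 1) < 1e-12))
  expect_identical(fx$factors, generate_lci_fixture(seed = 1)$factors)

  gw <- function(country) {
    mix <- dplyr::filter(fx$mixes, country_id == country)
    fac <- dplyr::filter(fx$factors, category_id == "global_warming")
    sum(mix$share * fac$factor[match(paste0("electricity_", mix$source_id),
                                     fac$flow_id)])
  }
  expect_gt(gw("coal_heavy"), gw("hydro_heavy"))
})
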