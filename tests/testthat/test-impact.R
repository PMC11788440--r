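toy_inventory <- function() {
  tibble::tibble(flow_id = c("a", "b"), amount = c(2, 3), unit = c("kg", "kg"))
}

toy_factors <- function() {
  tidyr::expand_grid(flow_id = c("a", "b"), category_id = c("c1", "c2")) |>
    dplyr::mutate(factor = c(10, 1, 0.5, 4))
}

test_that("characterization is the inventory-factor dot product", {
  inv <- toy_inventory()
  fac <- toy_factors()
  got <- characterize(inv, fac)
  # hand-computed: c1 = 2*10 + 3*0.5, c2 = 2*1 + 3*4
  expect_equal(got$score[got$category_id == "c1"], 21.5)
  expect_equal(got$score[got$category_id == "c2"], 14)

  # identity factor matrix returns the amounts
  id_fac <- tibble::tibble(flow_id = c("a", "b"),
                           category_id = c("a", "b"), factor = 1)
  ident <- characterize(inv, id_fac)
  expect_equal(ident$score[match(c("a", "b"), ident$category_id)], c(2, 3))

  zero <- inv; zero$amount <- 0
  expect_true(all(characterize(zero, fac)$score == 0))

  expect_error(characterize(tibble::tibble(flow_id = "zz", amount = 1), fac),
               regexp = "zz", class = "dwburden_domain_error")
})

test_that("characterization is additive in the inventory", {
  fac <- toy_factors()
  i1 <- toy_inventory()
  i2 <- toy_inventory(); i2$amount <- c(5, 0.5)
  sum_inv <- i1; sum_inv$amount <- i1$amount + i2$amount
  got <- characterize(sum_inv, fac)
  parts <- characterize(i1, fac)$score + characterize(i2, fac)$score
  expect_equal(got$score, parts)
})

test_that("electricity-mix resolution preserves energy and is linear", {
  fx <- generate_lci_fixture(seed = 1)
  inv <- fx$inventories$membrane
  kwh <- inv$amount[inv$flow_id == "electricity"]

  single <- tibble::tibble(source_id = "coal", share = 1)
  r1 <- apply_electricity_mix(inv, single)
  expect_equal(r1$amount[r1$flow_id == "electricity_coal"], kwh)

  fifty <- tibble::tibble(source_id = c("coal", "hydro"), share = c(0.5, 0.5))
  r5 <- apply_electricity_mix(inv, fifty)
  expect_equal(sum(r5$amount[grepl("^electricity_", r5$flow_id)]), kwh)

  # characterized 50/50 result is the mean of the single-source results
  fac <- fx$factors
  coal_only <- characterize(apply_electricity_mix(inv, single), fac)
  hydro_only <- characterize(
    apply_electricity_mix(inv, tibble::tibble(source_id = "hydro", share = 1)),
    fac
  )
  both <- characterize(r5, fac)
  expect_equal(both$score, (coal_only$score + hydro_only$score) / 2)

  bad <- tibble::tibble(source_id = c("coal", "gas"), share = c(0.6, 0.5))
  expect_error(apply_electricity_mix(inv, bad), class = "dwburden_domain_error")
})

test_that("mitigation scenarios rescale the targeted flows", {
  fx <- generate_lci_fixture(seed = 2)
  inv <- fx$inventories$membrane

  doubled <- apply_scenario(inv, scenario_spec(membrane_life_multiplier = 2))
  expect_equal(doubled$amount[doubled$flow_id == "membrane_replacement"],
               inv$amount[inv$flow_id == "membrane_replacement"] / 2)

  noop <- apply_scenario(inv, scenario_spec(energy_recovery_fraction = 0,
                                            hp_pump_share = 0.9))
  expect_identical(noop, inv)

  # half the electricity goes to high-pressure pumps; 30% of that recovered
  rec <- apply_scenario(inv, scenario_spec(energy_recovery_fraction = 0.3,
                                           hp_pump_share = 0.5))
  expect_equal(rec$amount[rec$flow_id == "electricity"],
               0.85 * inv$amount[inv$flow_id == "electricity"])

  swapped <- apply_scenario(inv, scenario_spec(
    transport_mode_swap = c(transport_truck = "transport_rail")
  ))
  expect_false("transport_truck" %in% swapped$flow_id)
  expect_equal(swapped$amount[swapped$flow_id == "transport_rail"],
               inv$amount[inv$flow_id == "transport_truck"])
  expect_equal(sum(swapped$amount), sum(inv$amount))

  expect_error(scenario_spec(membrane_life_multiplier = 0.5),
               class = "dwburden_domain_error")
  expect_error(scenario_spec(energy_recovery_fraction = 1),
               class = "dwburden_domain_error")
})

test_that("percent change reports reductions negatively", {
  base <- tibble::tibble(category_id = c("c1", "c2", "c3"),
                         score = c(10, 4, 0))
  alt <- base
  expect_true(all(percent_change(base, alt)$percent_change[1:2] == 0))

  alt2 <- base; alt2$score <- base$score * c(0.37, 1.53, 1)
  pc <- percent_change(base, alt2)
  expect_equal(pc$percent_change[1], -63)
  expect_equal(pc$percent_change[2], 53)
  expect_true(is.na(pc$percent_change[3])) # zero base is undefined

  # scaling identity across every nonzero category
  k <- 1.25
  altk <- base; altk$score <- base$score * k
  pck <- percent_change(base, altk)
  expect_equal(pck$percent_change[1:2], rep(100 * (k - 1), 2))
})
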