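#' Life-cycle impact characterization
#'
#' Transforms a foreground inventory (flow amounts per functional unit,
#' here 1 m³ of product water) into midpoint impact-category scores using
#' a user-supplied characterization matrix:
#' `score_c = sum_f amount_f * factor_{f,c}`. The engine is purely
#' data-driven — no characterization factors are bundled; synthetic
#' fixtures are available from [generate_lci_fixture()].
#'
#' @param inventory tibble with columns `flow_id`, `amount` (and
#'   optionally `unit`); amounts must be non-negative, flow ids unique.
#' @param factors tibble with columns `flow_id`, `category_id`, `factor`.
#' @return tibble with columns `category_id`, `score`, one row per
#'   category present in `factors`.
#' @examples
#' inv <- tibble::tibble(flow_id = c("a", "b"), amount = c(2, 3))
#' fac <- tibble::tibble(flow_id = c("a", "b"), category_id = "gw",
#'                       factor = c(10, 1))
#' characterize(inv, fac) # gw: 23
#' @export
characterize <- function(inventory, factors) {
  stopifnot(is.data.frame(inventory), is.data.frame(factors))
  if (anyDuplicated(inventory$flow_id)) stop_domain("inventory flow ids must be unique")
  if (any(inventory$amount < 0)) stop_domain("inventory amounts must be non-negative")
  missing <- setdiff(inventory$flow_id, unique(factors$flow_id))
  if (length(missing) > 0) {
    stop_domain(sprintf("no characterization factors for flow(s): %s",
                        paste(missing, collapse = ", ")))
  }
  cats <- unique(factors$category_id)
  inner_join(inventory, factors, by = "flow_id",
             relationship = "many-to-many") |>
    group_by(.data$category_id) |>
    summarise(score = sum(.data$amount * .data$factor), .groups = "drop") |>
    (\(d) left_join(tibble(category_id = cats), d, by = "category_id"))() |>
    mutate(score = ifelse(is.na(.data$score), 0, .data$score))
}

#' Resolve electricity consumption into a country generation mix
#'
#' Replaces each aggregate electricity flow (in kWh) by source-resolved
#' flows `electricity_<source>` weighted by the country's generation
#' shares, so that characterization then applies per-source factors.
#' Total kWh is preserved exactly.
#'
#' @param inventory tibble (`flow_id`, `amount`, optionally `unit`).
#' @param mix tibble with columns `source_id`, `share` for one country
#'   (shares must sum to 1 within 1e-9), e.g. one country slice of the
#'   `mixes` table from [generate_lci_fixture()].
#' @param elec_flows flow ids treated as aggregate electricity (default
#'   `"electricity"`).
#' @return the inventory with electricity resolved by source.
#' @export
apply_electricity_mix <- function(inventory, mix, elec_flows = "electricity") {
  stopifnot(is.data.frame(mix), all(c("source_id", "share") %in% names(mix)))
  if (any(mix$share < 0)) stop_domain("mix shares must be non-negative")
  if (abs(sum(mix$share) - 1) > 1e-9) {
    stop_domain(sprintf("mix shares must sum to 1 (got %.12g)", sum(mix$share)))
  }
  is_elec <- inventory$flow_id %in% elec_flows
  if (!any(is_elec)) return(inventory)
  kwh <- sum(inventory$amount[is_elec])
  resolved <- tibble(
    flow_id = paste0("electricity_", mix$source_id),
    amount = kwh * mix$share
  )
  if ("unit" %in% names(inventory)) resolved$unit <- "kWh"
  bind_rows(inventory[!is_elec, ], resolved)
}

#' Mitigation-scenario specification
#'
#' Describes the levers of the mitigation scenarios: extending membrane
#' life (replacement flow scales inversely with the life multiplier),
#' recovering energy from the high-pressure pump stage (electricity
#' scales by `1 - hp_pump_share * energy_recovery_fraction`), and swapping
#' transport modes (amounts move between mode-specific flow ids).
#'
#' @param membrane_life_multiplier >= 1; 2 means membranes last twice as
#'   long, halving the replacement flow.
#' @param energy_recovery_fraction fraction in `[0, 1)` of the
#'   high-pressure-pump electricity recovered (e.g. by a Pelton turbine).
#' @param hp_pump_share share in `[0, 1]` of total electricity drawn by
#'   high-pressure pumps (about 0.5 for a reverse-osmosis plant).
#' @param transport_mode_swap named character vector mapping transport
#'   flow ids to their replacement flow ids, e.g.
#'   `c(transport_truck = "transport_rail")`.
#' @param membrane_flow,electricity_flow flow ids the levers act on.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(membrane_life_multiplier = 1,
                          energy_recovery_fraction = 0,
                          hp_pump_share = 0,
                          transport_mode_swap = character(),
                          membrane_flow = "membrane_replacement",
                          electricity_flow = "electricity") {
  if (membrane_life_multiplier < 1) stop_domain("membrane_life_multiplier must be >= 1")
  if (energy_recovery_fraction < 0 || energy_recovery_fraction >= 1) {
    stop_domain("energy_recovery_fraction must be in [0, 1)")
  }
  if (hp_pump_share < 0 || hp_pump_share > 1) {
    stop_domain("hp_pump_share must be in [0, 1]")
  }
  structure(
    list(membrane_life_multiplier = membrane_life_multiplier,
         energy_recovery_fraction = energy_recovery_fraction,
         hp_pump_share = hp_pump_share,
         transport_mode_swap = transport_mode_swap,
         membrane_flow = membrane_flow,
         electricity_flow = electricity_flow),
    class = "scenario_spec"
  )
}

#' Apply a mitigation scenario to an inventory
#'
#' @param inventory tibble (`flow_id`, `amount`, ...).
#' @param scenario a [scenario_spec()].
#' @return the modified inventory tibble.
#' @export
apply_scenario <- function(inventory, scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  inv <- inventory
  im <- inv$flow_id == scenario$membrane_flow
  inv$amount[im] <- inv$amount[im] / scenario$membrane_life_multiplier
  ie <- inv$flow_id == scenario$electricity_flow
  inv$amount[ie] <- inv$amount[ie] *
    (1 - scenario$hp_pump_share * scenario$energy_recovery_fraction)
  swap <- scenario$transport_mode_swap
  for (from in names(swap)) {
    to <- swap[[from]]
    ifrom <- which(inv$flow_id == from)
    if (length(ifrom) == 0) next
    moved <- sum(inv$amount[ifrom])
    ito <- which(inv$flow_id == to)
    if (length(ito) == 0) {
      new_row <- inv[ifrom[1], ]
      new_row$flow_id <- to
      new_row$amount <- moved
      inv <- bind_rows(inv, new_row)
    } else {
      inv$amount[ito[1]] <- inv$amount[ito[1]] + moved
    }
    inv <- inv[-ifrom, ]
  }
  inv
}

#' Percent change between two impact profiles
#'
#' `100 * (alt - base) / base` per category; negative values are
#' reductions. Categories with zero base score are flagged undefined.
#'
#' @param base,alt tibbles from [characterize()] (`category_id`, `score`).
#' @return tibble with `category_id`, `base`, `alt`, `percent_change`.
#' @export
percent_change <- function(base, alt) {
  j <- inner_join(rename(base, base = "score"),
                  rename(alt, alt = "score"), by = "category_id")
  j |> mutate(percent_change = ifelse(.data$base == 0, NA_real_,
                                      100 * (.data$alt - .data$base) / .data$base))
}
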