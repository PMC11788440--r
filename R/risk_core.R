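#' Exposure context for burden calculations
#'
#' Bundles the population and exposure constants of the burden model: the
#' population served by the plant (`sp`), the average daily drinking-water
#' ingestion rate, the exposure horizon in years, the damage factors
#' converting disease cases into DALYs for each endpoint, and the tolerable
#' disease-burden threshold against which compliance is judged.
#'
#' Defaults correspond to a plant serving 500,000 people, 1.4 L/day
#' ingestion over a 25-year service life, damage factors of 2.7 DALYs per
#' non-cancer case and 11.5 DALYs per cancer case, and the WHO tolerable
#' burden of 1.00e-6 DALYs per person per year.
#'
#' @param sp population served (persons).
#' @param ir_daily daily ingestion rate (L/day).
#' @param years exposure horizon (years).
#' @param df_cancer,df_noncancer damage factors (DALYs/case).
#' @param threshold tolerable burden (DALYs person^-1 year^-1).
#' @return an `exposure_context` object.
#' @examples
#' ctx <- exposure_context()
#' cumulative_intake(ctx) # 12775 L over 25 years
#' @export
exposure_context <- function(sp = 500000, ir_daily = 1.4, years = 25,
                             df_cancer = 11.5, df_noncancer = 2.7,
                             threshold = 1e-6) {
  check_scalar_number(sp, "sp", 0, strict_min = TRUE)
  check_scalar_number(ir_daily, "ir_daily", 0, strict_min = TRUE)
  check_scalar_number(years, "years", 0, strict_min = TRUE)
  check_scalar_number(df_cancer, "df_cancer", 0, strict_min = TRUE)
  check_scalar_number(df_noncancer, "df_noncancer", 0, strict_min = TRUE)
  check_scalar_number(threshold, "threshold", 0, strict_min = TRUE)
  structure(
    list(sp = sp, ir_daily = ir_daily, years = years,
         df_cancer = df_cancer, df_noncancer = df_noncancer,
         threshold = threshold),
    class = "exposure_context"
  )
}

#' @export
print.exposure_context <- function(x, ...) {
  cat("<exposure_context>\n")
  cat(sprintf("  population served : %g persons\n", x$sp))
  cat(sprintf("  ingestion         : %g L/day over %g y (%g L total)\n",
              x$ir_daily, x$years, cumulative_intake(x)))
  cat(sprintf("  damage factors    : cancer %g, non-cancer %g DALYs/case\n",
              x$df_cancer, x$df_noncancer))
  cat(sprintf("  threshold         : %g DALYs person^-1 y^-1\n", x$threshold))
  invisible(x)
}

damage_factor <- function(ctx, endpoint) {
  endpoint <- match.arg(endpoint, c("cancer", "noncancer"))
  if (endpoint == "cancer") ctx$df_cancer else ctx$df_noncancer
}

#' Residual concentration after a treatment train
#'
#' The residual concentration of a chemical after an ordered series of
#' treatment units is the source-water concentration multiplied by the
#' retained fraction of every unit: `ce = cs * prod(1 - r_k)`. Units act
#' independently and multiplicatively, so permuting them does not change
#' the result.
#'
#' @param cs source-water concentration (ng/L), scalar or vector.
#' @param removals numeric vector of per-unit removal fractions in `[0, 1]`
#'   (for vector `cs`, a matrix with one column per unit also works).
#' @return residual concentration (ng/L), never negative, never above `cs`.
#' @examples
#' residual_concentration(100, c(0.5, 0.8)) # 10
#' @export
residual_concentration <- function(cs, removals) {
  if (any(cs < 0)) stop_domain("`cs` must be non-negative")
  if (length(removals) == 0) return(cs)
  r <- as.numeric(removals)
  bad <- which(r < 0 | r > 1)
  if (length(bad) > 0) {
    stop_domain(sprintf(
      "removal fraction outside [0, 1] at unit index %s",
      paste(bad, collapse = ", ")
    ))
  }
  if (is.matrix(removals)) {
    cs * apply(1 - removals, 1, prod)
  } else {
    cs * prod(1 - r)
  }
}

#' Cumulative per-capita water intake
#'
#' Total volume of drinking water one person consumes over the exposure
#' horizon: `ir_daily * 365 * years`.
#'
#' @param ctx an [exposure_context()].
#' @return volume in litres.
#' @export
cumulative_intake <- function(ctx) {
  stopifnot(inherits(ctx, "exposure_context"))
  ctx$ir_daily * 365 * ctx$years
}

#' Population-level ingested mass of a chemical
#'
#' Mass of chemical ingested by the whole served population over the
#' exposure horizon: `sp * intake_l * ce * 1e-12` kg, with `ce` in ng/L
#' (1 ng/L = 1e-12 kg/L).
#'
#' @param sp population served (persons).
#' @param intake_l per-capita cumulative intake (L), see
#'   [cumulative_intake()].
#' @param ce residual concentration (ng/L).
#' @return ingested mass in kg.
#' @export
ingested_mass <- function(sp, intake_l, ce) {
  if (any(c(sp, intake_l) < 0) || any(ce < 0)) {
    stop_domain("ingested_mass inputs must be non-negative")
  }
  sp * intake_l * ce * 1e-12
}

#' Health effect of one chemical
#'
#' One chemical's contribution to the population disease burden over the
#' exposure horizon: `ef * df * intake_kg` DALYs, where `ef` is the
#' endpoint effect factor (cases/kg of intake) and `df` the damage factor
#' (DALYs/case).
#'
#' @param ef effect factor (cases/kg).
#' @param df damage factor (DALYs/case).
#' @param intake_kg ingested mass (kg), see [ingested_mass()].
#' @return burden in DALYs (population total over the horizon).
#' @export
health_effect <- function(ef, df, intake_kg) {
  if (any(c(ef, df) < 0) || any(intake_kg < 0)) {
    stop_domain("health_effect inputs must be non-negative")
  }
  ef * df * intake_kg
}

#' Annualized per-person burden
#'
#' Normalizes a population total over the exposure horizon onto the
#' per-person, per-year scale used for threshold compliance:
#' `he / (sp * years)`.
#'
#' @param he population burden over the horizon (DALYs).
#' @param ctx an [exposure_context()].
#' @return DALYs person^-1 year^-1.
#' @export
annual_per_person <- function(he, ctx) {
  stopifnot(inherits(ctx, "exposure_context"))
  if (any(he < 0)) stop_domain("`he` must be non-negative")
  he / (ctx$sp * ctx$years)
}

#' Aggregate per-chemical burdens under a mixture-toxicity convention
#'
#' Combines per-chemical annual per-person burdens into a mixture total.
#' Three conventions are supported:
#'
#' * `additive` (default, conservative): the sum of individual burdens.
#' * `dominant`: the worst single contributor (the maximum).
#' * `multiplicative`: independent action (response addition) on the
#'   per-person lifetime case probabilities `p_i`; the combined probability
#'   `1 - prod(1 - p_i)` is converted back to an annual per-person burden
#'   with the endpoint damage factor. For small risks this converges to the
#'   additive total.
#'
#' For `multiplicative`, per-chemical lifetime case probabilities must be
#' supplied; they are `ef_i * if_i / sp` in the underlying model. The
#' conversion back to DALYs uses `df * p_combined / years`.
#'
#' @param per_cec numeric vector of per-chemical burdens
#'   (DALYs person^-1 y^-1), all non-negative.
#' @param mode `"additive"`, `"dominant"` or `"multiplicative"`.
#' @param per_cec_case_prob per-person lifetime case probabilities in
#'   `[0, 1)`; required for `multiplicative`.
#' @param ctx an [exposure_context()]; required for `multiplicative`.
#' @param endpoint `"cancer"` or `"noncancer"`; selects the damage factor
#'   for `multiplicative`.
#' @return aggregated burden (DALYs person^-1 y^-1).
#' @examples
#' aggregate_mixture(c(2e-7, 3e-7), mode = "additive") # 5e-7
#' aggregate_mixture(c(2e-7, 3e-7), mode = "dominant") # 3e-7
#' @export
aggregate_mixture <- function(per_cec, mode = c("additive", "dominant", "multiplicative"),
                              per_cec_case_prob = NULL, ctx = NULL,
                              endpoint = c("cancer", "noncancer")) {
  mode <- match.arg(mode)
  if (any(per_cec < 0)) stop_domain("per-chemical burdens must be non-negative")
  if (mode == "additive") return(sum(per_cec))
  if (mode == "dominant") {
    return(if (length(per_cec) == 0) 0 else max(per_cec))
  }
  # multiplicative: independent action on case probabilities
  endpoint <- match.arg(endpoint)
  if (is.null(per_cec_case_prob) || is.null(ctx)) {
    stop_usage("multiplicative mode requires `per_cec_case_prob` and `ctx`")
  }
  p <- per_cec_case_prob
  if (any(p < 0)) stop_domain("case probabilities must be non-negative")
  if (any(p >= 1)) stop_domain("case probabilities must be < 1")
  p_comb <- 1 - prod(1 - p)
  damage_factor(ctx, endpoint) * p_comb / ctx$years
}

#' Per-person lifetime case probability of one chemical
#'
#' `ef * intake_kg / sp`: the expected number of disease cases per person
#' over the exposure horizon, the quantity combined under the
#' independent-action mixture convention.
#'
#' @inheritParams health_effect
#' @param sp population served.
#' @return probability (cases per person over the horizon).
#' @export
case_probability <- function(ef, intake_kg, sp) {
  if (any(c(ef, sp) < 0) || any(intake_kg < 0)) {
    stop_domain("case_probability inputs must be non-negative")
  }
  ef * intake_kg / sp
}

# --- burden table -----------------------------------------------------------

# internal: evaluate a dist triple at its mode (point evaluation)
point_of <- function(low, mode, high) mode

#' Deterministic burden breakdown for a chemical table
#'
#' Evaluates the full exposure-to-burden chain for every chemical at point
#' values (by default the mode of each input distribution) and reports
#' per-chemical, per-category and total burdens for both endpoints.
#' Chemicals lacking an effect factor for an endpoint are excluded from
#' that endpoint only. `train = NULL` evaluates the source water (no
#' removal).
#'
#' @param cecs a CEC table, as returned by [read_cec_table()] or
#'   [generate_cec_dataset()]: one row per chemical with columns `cec_id`,
#'   `category`, `conc_low/mode/high`, `ef_cancer`, `ef_noncancer`.
#' @param train a treatment train (see [make_train()]) or `NULL` for raw
#'   source water.
#' @param ctx an [exposure_context()].
#' @param point_sampler a function `(low, mode, high) -> value` used to
#'   collapse each input distribution to a point; defaults to the mode.
#' @param mixture_mode aggregation convention for totals, see
#'   [aggregate_mixture()].
#' @return a list of class `burden_breakdown` with tibbles `per_cec`
#'   (columns `cec_id`, `category`, `endpoint`, `ce`, `intake_kg`, `he`,
#'   `annual_per_person`), `per_category` and `totals`.
#' @export
burden_table <- function(cecs, train = NULL, ctx = exposure_context(),
                         point_sampler = point_of,
                         mixture_mode = "additive") {
  if (!is.data.frame(cecs) || nrow(cecs) == 0) {
    stop_usage("`cecs` must be a non-empty CEC table")
  }
  stopifnot(inherits(ctx, "exposure_context"))
  intake_l <- cumulative_intake(ctx)

  cs <- mapply(point_sampler, cecs$conc_low, cecs$conc_mode, cecs$conc_high)

  if (!is.null(train)) {
    rem <- removal_matrix_point(train, cecs$cec_id, point_sampler)
    ce <- residual_concentration(cs, rem)
  } else {
    ce <- cs
  }
  intake_kg <- ingested_mass(ctx$sp, intake_l, ce)

  per_endpoint <- function(endpoint) {
    ef <- if (endpoint == "cancer") cecs$ef_cancer else cecs$ef_noncancer
    keep <- !is.na(ef)
    df <- damage_factor(ctx, endpoint)
    he <- health_effect(ef[keep], df, intake_kg[keep])
    tibble(
      cec_id = cecs$cec_id[keep],
      category = cecs$category[keep],
      endpoint = endpoint,
      ce = ce[keep],
      intake_kg = intake_kg[keep],
      he = he,
      annual_per_person = annual_per_person(he, ctx),
      case_prob = case_probability(ef[keep], intake_kg[keep], ctx$sp)
    )
  }
  per_cec <- bind_rows(per_endpoint("cancer"), per_endpoint("noncancer"))

  per_category <- per_cec |>
    group_by(.data$endpoint, .data$category) |>
    summarise(
      annual_per_person = sum(.data$annual_per_person),
      he = sum(.data$he),
      n_cec = n(),
      .groups = "drop"
    )

  totals <- per_cec |>
    group_by(.data$endpoint) |>
    summarise(
      annual_per_person = aggregate_mixture(
        .data$annual_per_person, mode = mixture_mode,
        per_cec_case_prob = .data$case_prob, ctx = ctx,
        endpoint = .data$endpoint[1]
      ),
      n_cec = n(),
      .groups = "drop"
    )

  structure(
    list(per_cec = per_cec, per_category = per_category, totals = totals,
         mixture_mode = mixture_mode),
    class = "burden_breakdown"
  )
}

#' @export
print.burden_breakdown <- function(x, ...) {
  cat(sprintf("<burden_breakdown: %d chemical-endpoint records, %s mixture>\n",
              nrow(x$per_cec), x$mixture_mode))
  print(x$totals)
  invisible(x)
}

# internal: n_cec x n_unit matrix of point removal values for a train
removal_matrix_point <- function(train, cec_ids, point_sampler = point_of) {
  stopifnot(inherits(train, "treatment_train"))
  out <- matrix(0, nrow = length(cec_ids), ncol = length(train$units),
                dimnames = list(cec_ids, names(train$units)))
  for (j in seq_along(train$units)) {
    unit <- train$units[[j]]
    miss <- setdiff(cec_ids, unit$removal$cec_id)
    if (length(miss) > 0) {
      stop_usage(sprintf(
        "unit '%s' lacks removal data for: %s (impute first)",
        unit$unit_id, paste(head(miss, 5), collapse = ", ")
      ))
    }
    idx <- match(cec_ids, unit$removal$cec_id)
    out[, j] <- mapply(point_sampler,
                       unit$removal$r_low[idx],
                       unit$removal$r_mode[idx],
                       unit$removal$r_high[idx])
  }
  out
}
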