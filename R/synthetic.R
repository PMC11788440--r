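#' Configuration for the synthetic study-input generator
#'
#' The generator emulates the statistical structure of a realistic
#' chemicals-of-emerging-concern (CEC) screening dataset: 93 chemicals in
#' six categories (41 pesticides, 19 industrial chemicals, 17
#' pharmaceuticals, 7 antibiotics, 5 disinfection byproducts, 4 personal
#' care products), influent concentrations spanning roughly ng/L to µg/L,
#' effect factors spanning several orders of magnitude (~1e-3 to ~1e1
#' cases/kg) with disinfection byproducts biased toward the high-toxicity
#' tail, per-unit removal profiles typical of each treatment technology,
#' a fraction of missing removal entries (exercising category-mean
#' imputation) and a fraction of detection-limit-censored concentrations.
#'
#' @param category_counts named integer vector of chemicals per category.
#' @param conc_log10_range log10 range (ng/L) for influent concentration
#'   modes, sampled log-uniformly.
#' @param ef_log10_range log10 range (cases/kg) for effect factors.
#' @param removal_profiles named list: unit process -> `c(low, high)` range
#'   from which the removal-fraction mode of each chemical is drawn.
#' @param missing_removal_frac fraction of (unit, chemical) removal entries
#'   deleted to exercise imputation.
#' @param censored_frac fraction of chemicals whose concentration is
#'   reported only as below a detection limit.
#' @param rel_half_width relative half-width of the triangular spread put
#'   around each sampled mode.
#' @param p_cancer_ef probability a chemical has a cancer effect factor
#'   (disinfection byproducts always do; non-cancer factors are always
#'   present).
#' @param seed integer seed; every artifact draws from its own named
#'   sub-stream of this seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(category_counts = c(pesticide = 41, industrial = 19,
                                             pharmaceutical = 17, antibiotic = 7,
                                             DBP = 5, PCP = 4),
                         conc_log10_range = c(0, 3),
                         ef_log10_range = c(-3, 1.1),
                         removal_profiles = default_removal_profiles(),
                         missing_removal_frac = 0.05,
                         censored_frac = 0.1,
                         rel_half_width = 0.5,
                         p_cancer_ef = 0.7,
                         seed = 1) {
  if (any(category_counts < 0) || sum(category_counts) == 0) {
    stop_usage("category counts must be non-negative and sum to > 0")
  }
  if (!all(names(category_counts) %in% cec_categories())) {
    stop_usage("category_counts names must be valid categories")
  }
  stopifnot(missing_removal_frac >= 0, missing_removal_frac <= 1,
            censored_frac >= 0, censored_frac <= 1,
            rel_half_width >= 0, rel_half_width < 1,
            diff(conc_log10_range) >= 0, diff(ef_log10_range) >= 0)
  structure(
    list(category_counts = category_counts,
         conc_log10_range = conc_log10_range,
         ef_log10_range = ef_log10_range,
         removal_profiles = removal_profiles,
         missing_removal_frac = missing_removal_frac,
         censored_frac = censored_frac,
         rel_half_width = rel_half_width,
         p_cancer_ef = p_cancer_ef,
         seed = seed),
    class = "synth_config"
  )
}

#' @rdname synth_config
#' @export
default_removal_profiles <- function() {
  list(
    rbf = c(0.30, 0.70),
    coagulation = c(0.10, 0.40),
    sedimentation = c(0.05, 0.20),
    sand_filtration = c(0.05, 0.30),
    ultrafiltration = c(0.20, 0.60),
    ozonation = c(0.30, 0.80),
    activated_carbon = c(0.40, 0.90),
    reverse_osmosis = c(0.90, 0.99),
    chlorination = c(0.10, 0.50)
  )
}

# the two emulated system layouts: a 6-unit membrane train and a 7-unit
# conventional extended train, both headed by riverbank filtration
synthetic_train_defs <- function() {
  list(
    rbf_ro = list(
      train_id = "rbf_ro",
      units = tibble(
        unit_id = c("rbf", "coagulation", "sand_filtration",
                    "ultrafiltration", "reverse_osmosis", "chlorination"),
        name = c("riverbank filtration", "coagulation/flocculation",
                 "rapid sand filtration", "ultrafiltration",
                 "reverse osmosis", "chlorination")
      )
    ),
    rbf_et = list(
      train_id = "rbf_et",
      units = tibble(
        unit_id = c("rbf", "coagulation", "sedimentation", "sand_filtration",
                    "ozonation", "activated_carbon", "chlorination"),
        name = c("riverbank filtration", "coagulation/flocculation",
                 "sedimentation", "rapid sand filtration", "ozonation",
                 "granular activated carbon", "chlorination")
      )
    )
  )
}

#' Generate a synthetic CEC dataset with two treatment trains
#'
#' Draws a full study-input bundle from a [synth_config()]: the chemical
#' table (with censored rows encoded as blank concentrations plus an LOD),
#' a long removal table for a 6-unit membrane train and a 7-unit extended
#' train (with the requested fraction of entries deleted), and the
#' assembled, imputation-completed `treatment_train` objects. The same
#' seed always yields the same bundle.
#'
#' @param cfg a [synth_config()].
#' @return list with elements `cecs` (validated, censoring applied),
#'   `cecs_raw` (as written to file, blanks intact), `removals` (long
#'   tibble for both trains, missing entries absent), `train_defs`,
#'   `trains` (assembled `treatment_train` objects) and `config`.
#' @export
generate_cec_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  seed <- cfg$seed
  counts <- cfg$category_counts[cfg$category_counts > 0]
  n <- sum(counts)
  category <- rep(names(counts), counts)
  cec_id <- sprintf("cec%03d", seq_len(n))

  # influent concentration: log-uniform mode, triangular spread around it
  lg <- cfg$conc_log10_range
  u_c <- substream_runif(n, seed, "synth/conc_mode")
  conc_mode <- 10^(lg[1] + u_c * (lg[2] - lg[1]))
  w <- cfg$rel_half_width
  conc_low <- conc_mode * (1 - w)
  conc_high <- conc_mode * (1 + w)

  # effect factors: log-uniform; DBPs drawn from the top of the range
  eg <- cfg$ef_log10_range
  draw_ef <- function(u, dbp) {
    lo <- ifelse(dbp, eg[1] + 0.7 * diff(eg), eg[1])
    10^(lo + u * (eg[2] - lo))
  }
  is_dbp <- category == "DBP"
  ef_noncancer <- draw_ef(substream_runif(n, seed, "synth/ef_nc"), is_dbp)
  ef_cancer <- draw_ef(substream_runif(n, seed, "synth/ef_ca"), is_dbp)
  has_ca <- substream_runif(n, seed, "synth/has_cancer") < cfg$p_cancer_ef | is_dbp
  ef_cancer[!has_ca] <- NA_real_

  # censoring: selected chemicals reported only as < LOD
  cens <- substream_runif(n, seed, "synth/censored") < cfg$censored_frac
  lod <- rep(NA_real_, n)
  u_l <- substream_runif(n, seed, "synth/lod")
  lod[cens] <- 10^(-1 + 1.5 * u_l[cens]) # 0.1 - ~3 ng/L detection limits

  cecs_raw <- tibble(
    cec_id = cec_id,
    name = paste0("synthetic-", category, "-", cec_id),
    category = category,
    conc_low = ifelse(cens, NA_real_, conc_low),
    conc_mode = ifelse(cens, NA_real_, conc_mode),
    conc_high = ifelse(cens, NA_real_, conc_high),
    lod = lod,
    loq = NA_real_,
    ef_cancer = ef_cancer,
    ef_noncancer = ef_noncancer
  )
  cecs <- suppressWarnings(validate_cec_table(cecs_raw))

  # removal tables for both trains
  defs <- synthetic_train_defs()
  removals <- bind_rows(lapply(defs, function(d) {
    bind_rows(lapply(d$units$unit_id, function(uid) {
      rng <- cfg$removal_profiles[[uid]]
      if (is.null(rng)) stop_usage(sprintf("no removal profile for unit '%s'", uid))
      u <- substream_runif(n, seed, paste0("synth/removal/", d$train_id, "/", uid))
      m <- rng[1] + u * (rng[2] - rng[1])
      tibble(
        train_id = d$train_id, unit_id = uid, cec_id = cec_id,
        r_low = m * (1 - w),
        r_mode = m,
        r_high = pmin(1, m * (1 + w))
      )
    }))
  }))

  # delete entries to exercise category-mean imputation, keeping at least
  # one donor per (train, unit, category)
  if (cfg$missing_removal_frac > 0) {
    u_m <- substream_runif(nrow(removals), seed, "synth/missing")
    drop <- u_m < cfg$missing_removal_frac
    cat_of <- category[match(removals$cec_id, cec_id)]
    key <- paste(removals$train_id, removals$unit_id, cat_of)
    for (k in unique(key[drop])) {
      rows <- which(key == k)
      if (all(drop[rows])) drop[rows[1]] <- FALSE
    }
    removals <- removals[!drop, ]
  }

  trains <- lapply(defs, function(d) assemble_train(d, removals, cecs))

  list(cecs = cecs, cecs_raw = cecs_raw, removals = removals,
       train_defs = defs, trains = trains, config = cfg)
}

#' Two-system benchmark with planted dominance and known expectations
#'
#' Builds a small paired-train scenario in which the membrane-style train
#' is constructed to dominate the conventional-style train: every possible
#' residual fraction of the 6-unit membrane train lies strictly below
#' every possible residual fraction of the 7-unit conventional train, for
#' every chemical. Under shared source-water draws this guarantees the
#' per-iteration burden ordering, so the paired benefit fraction is 100%
#' by construction. Analytic expected burdens (from triangular means and
#' unit independence) are returned alongside for recovery tests.
#'
#' @param seed integer seed.
#' @param n_cec number of chemicals in the benchmark set.
#' @return list with `cecs`, `trains` (named: `conventional`, `membrane`),
#'   `ctx`, and `ground_truth` (tibble of analytic expected endpoint
#'   totals per train, DALYs person^-1 y^-1).
#' @export
generate_two_system_benchmark <- function(seed = 1, n_cec = 10) {
  cats <- rep_len(c("pesticide", "industrial", "pharmaceutical", "DBP"), n_cec)
  cec_id <- sprintf("bm%02d", seq_len(n_cec))
  u1 <- substream_runif(n_cec, seed, "bench/conc")
  conc_mode <- 10^(1 + 2 * u1)
  u2 <- substream_runif(n_cec, seed, "bench/ef")
  ef <- 10^(-2 + 2.5 * u2)
  cecs <- tibble(
    cec_id = cec_id, name = paste0("benchmark-", cec_id), category = cats,
    conc_low = conc_mode * 0.5, conc_mode = conc_mode,
    conc_high = conc_mode * 1.5,
    lod = NA_real_, loq = NA_real_,
    ef_cancer = ef, ef_noncancer = ef * 0.5,
    censored = FALSE
  )

  unit_tbl <- function(ids) tibble(unit_id = ids, name = ids)
  rem_tbl <- function(tid, ids, lo, mo, hi) {
    tidyr::expand_grid(unit_id = ids, cec_id = cec_id) |>
      mutate(train_id = tid, r_low = lo, r_mode = mo, r_high = hi)
  }
  # conventional: per-unit removal in [0.5, 0.7] over 7 units -> residual
  # fraction in [0.3^7, 0.5^7]; membrane: removal in [0.8, 0.9] over 6
  # units -> residual in [0.1^6, 0.2^6]; max(membrane) < min(conventional)
  conv_ids <- paste0("conv_u", 1:7)
  memb_ids <- paste0("memb_u", 1:6)
  conv <- make_train("conventional", unit_tbl(conv_ids),
                     rem_tbl("conventional", conv_ids, 0.5, 0.6, 0.7))
  memb <- make_train("membrane", unit_tbl(memb_ids),
                     rem_tbl("membrane", memb_ids, 0.8, 0.85, 0.9))

  ctx <- exposure_context()
  e_cs <- (cecs$conc_low + cecs$conc_mode + cecs$conc_high) / 3
  expected <- function(train, endpoint) {
    retain <- prod(vapply(train$units, function(u) {
      1 - (u$removal$r_low[1] + u$removal$r_mode[1] + u$removal$r_high[1]) / 3
    }, numeric(1)))
    efv <- if (endpoint == "cancer") cecs$ef_cancer else cecs$ef_noncancer
    df <- damage_factor(ctx, endpoint)
    sum(efv * df * ctx$ir_daily * 365 * 1e-12 * e_cs * retain)
  }
  ground_truth <- tidyr::expand_grid(
    train = c("conventional", "membrane"),
    endpoint = c("cancer", "noncancer")
  ) |>
    mutate(expected_total = purrr::map2_dbl(
      .data$train, .data$endpoint,
      function(tr, ep) expected(if (tr == "conventional") conv else memb, ep)
    ))

  list(cecs = cecs, trains = list(conventional = conv, membrane = memb),
       ctx = ctx, ground_truth = ground_truth)
}

#' Synthetic life-cycle inventory fixture
#'
#' Builds a self-contained, clearly synthetic life-cycle dataset: two
#' system inventories (membrane-style and conventional-style, per m³ of
#' product water), a characterization matrix over 10 midpoint impact
#' categories, per-source electricity factors for six generation sources,
#' and three country electricity mixes whose shares sum to one. The
#' global-warming factors of the sources are planted in a fixed order
#' (coal > gas > solar > wind > nuclear > hydro) so mix comparisons have a
#' known direction. Factors are synthetic and carry no relation to any
#' licensed characterization database.
#'
#' @param seed integer seed.
#' @return list with `inventories` (named list of tibbles `flow_id`,
#'   `amount`, `unit`), `factors` (tibble `flow_id`, `category_id`,
#'   `factor`, `unit`), `mixes` (tibble `country_id`, `source_id`,
#'   `share`) and `categories`.
#' @export
generate_lci_fixture <- function(seed = 1) {
  categories <- c("global_warming", "ozone_depletion", "terrestrial_acidification",
                  "freshwater_eutrophication", "marine_eutrophication",
                  "terrestrial_ecotoxicity", "freshwater_ecotoxicity",
                  "marine_ecotoxicity", "mineral_consumption", "fossil_depletion")
  sources <- c("coal", "gas", "solar", "wind", "nuclear", "hydro")
  gw_per_kwh <- c(coal = 1.05, gas = 0.5, solar = 0.05, wind = 0.02,
                  nuclear = 0.012, hydro = 0.01)

  process_flows <- c("chemicals_coagulant", "chemicals_antiscalant",
                     "membrane_replacement", "transport_truck",
                     "transport_rail", "sludge_disposal")
  n_f <- length(process_flows)
  fac_rows <- list()
  for (ci in seq_along(categories)) {
    u <- substream_runif(n_f, seed, paste0("lci/factor/", categories[ci]))
    fac_rows[[ci]] <- tibble(
      flow_id = process_flows, category_id = categories[ci],
      factor = 10^(-3 + 3 * u), unit = "cat-unit/flow-unit"
    )
  }
  # per-source electricity factors; global warming planted in fixed order,
  # other categories loosely proportional with jitter
  for (ci in seq_along(categories)) {
    u <- substream_runif(length(sources), seed, paste0("lci/elec/", categories[ci]))
    base <- gw_per_kwh[sources]
    fac <- if (categories[ci] == "global_warming") base else base * (0.5 + u)
    fac_rows[[length(fac_rows) + 1]] <- tibble(
      flow_id = paste0("electricity_", sources), category_id = categories[ci],
      factor = unname(fac), unit = "cat-unit/kWh"
    )
  }
  factors <- bind_rows(fac_rows)

  inventories <- list(
    membrane = tibble(
      flow_id = c("electricity", "chemicals_coagulant", "chemicals_antiscalant",
                  "membrane_replacement", "transport_truck", "sludge_disposal"),
      amount = c(0.75, 0.02, 0.005, 1.2e-4, 0.01, 0.03),
      unit = c("kWh", "kg", "kg", "m2", "tkm", "kg")
    ),
    conventional = tibble(
      flow_id = c("electricity", "chemicals_coagulant", "transport_truck",
                  "sludge_disposal"),
      amount = c(0.45, 0.06, 0.02, 0.08),
      unit = c("kWh", "kg", "tkm", "kg")
    )
  )

  mixes <- bind_rows(
    tibble(country_id = "coal_heavy", source_id = c("coal", "gas", "hydro"),
           share = c(0.7, 0.2, 0.1)),
    tibble(country_id = "hydro_heavy", source_id = c("hydro", "wind", "nuclear"),
           share = c(0.8, 0.1, 0.1)),
    tibble(country_id = "balanced",
           source_id = c("coal", "gas", "solar", "wind", "hydro"),
           share = c(0.2, 0.2, 0.2, 0.2, 0.2))
  )

  list(inventories = inventories, factors = factors, mixes = mixes,
       categories = categories)
}
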