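# Small in-code fixtures shared across test files.

# a CEC table of point distributions (no sampling uncertainty)
point_cecs <- function(conc = c(4.6, 120), ef_ca = c(11.9, 0.07),
                       ef_nc = c(0.5, 0.01),
                       category = c("DBP", "industrial")) {
  n <- length(conc)
  tibble::tibble(
    cec_id = sprintf("p%02d", seq_len(n)),
    name = paste0("point-", seq_len(n)),
    category = rep_len(category, n),
    conc_low = conc, conc_mode = conc, conc_high = conc,
    lod = NA_real_, loq = NA_real_,
    ef_cancer = ef_ca, ef_noncancer = ef_nc,
    censored = FALSE
  )
}

# a train whose units all remove a fixed point fraction from every chemical
point_train <- function(cec_ids, removals, train_id = "pt") {
  units <- tibble::tibble(
    unit_id = sprintf("u%d", seq_along(removals)),
    name = sprintf("unit %d", seq_along(removals))
  )
  rem <- tidyr::expand_grid(unit_id = units$unit_id, cec_id = cec_ids) |>
    dplyr::mutate(
      train_id = train_id,
      r = removals[match(unit_id, units$unit_id)],
      r_low = r, r_mode = r, r_high = r
    ) |>
    dplyr::select(-r)
  make_train(train_id, units, rem)
}

# independently coded one-line burden chain (the composition oracle):
# EF*DF*SP*IR_daily*365*T*CS*prod(1-R)*1e-12 / (SP*T)
oracle_burden <- function(ef, df, cs, removals, sp = 500000, ir_daily = 1.4,
                          years = 25) {
  ef * df * sp * ir_daily * 365 * years * cs * prod(1 - removals) * 1e-12 /
    (sp * years)
}
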