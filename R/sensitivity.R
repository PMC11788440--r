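#' Spearman rank correlation
#'
#' Tie-aware Spearman's rank-order correlation: the Pearson correlation of
#' average-ranked data. Returns `NA` (flagged undefined) when either
#' vector is constant, since ranks carry no information there.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return correlation in `[-1, 1]`, or `NA_real_` if undefined.
#' @examples
#' spearman_rho(1:3, c(10, 20, 30)) # 1
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_usage("spearman_rho needs two equal-length vectors of length >= 3")
  }
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Monte Carlo input-output sensitivity (Spearman)
#'
#' Correlates every recorded input draw of a Monte Carlo run (each
#' chemical's influent concentration, each unit's per-chemical removal
#' rate) with the endpoint burden total across iterations, ranking the
#' inputs that drive the output uncertainty. Requires the run to have
#' stored its draws (`keep_draws = TRUE` in [run_mc()]).
#'
#' @param mc an `mc_result` with stored draws.
#' @param endpoint `"cancer"` or `"noncancer"`.
#' @return tibble with columns `parameter` (`cs:<cec>` or
#'   `removal:<unit>:<cec>`), `cec_id`, `unit_id`, `rho`, sorted by
#'   `|rho|` descending.
#' @export
mc_sensitivity <- function(mc, endpoint = c("cancer", "noncancer")) {
  stopifnot(inherits(mc, "mc_result"))
  endpoint <- match.arg(endpoint)
  if (is.null(mc$draws)) {
    stop_usage("run_mc() must be called with keep_draws = TRUE for sensitivity analysis")
  }
  out <- mc$totals[[endpoint]]
  rows <- list()
  cs <- mc$draws$cs
  for (id in colnames(cs)) {
    rows[[length(rows) + 1]] <- tibble(
      parameter = paste0("cs:", id), cec_id = id, unit_id = NA_character_,
      rho = spearman_rho_or_na(cs[, id], out)
    )
  }
  for (uid in names(mc$draws$removals)) {
    r <- mc$draws$removals[[uid]]
    for (id in colnames(r)) {
      rows[[length(rows) + 1]] <- tibble(
        parameter = paste0("removal:", uid, ":", id), cec_id = id,
        unit_id = uid, rho = spearman_rho_or_na(r[, id], out)
      )
    }
  }
  bind_rows(rows) |> arrange(dplyr::desc(abs(.data$rho)))
}

spearman_rho_or_na <- function(x, y) {
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' One-factor-at-a-time sensitivity coefficients
#'
#' Perturbs one model input by ±`delta` (default ±20%) around its base
#' value and reports the sensitivity coefficient — the ratio of the
#' relative output change to the relative input change — for each
#' direction, plus their mean (the headline value):
#' `sc = ((f(x(1±delta)) - f(x)) / f(x)) / (±delta)`.
#'
#' @param model a function of one numeric argument returning a numeric
#'   scalar (or named vector, treated element-wise).
#' @param base base input value.
#' @param delta relative perturbation (default 0.20).
#' @return tibble with columns `output` (names of the model value, or
#'   `"output"`), `sc_plus`, `sc_minus`, `sc_mean`. Outputs with base
#'   value 0 are flagged undefined (`NA`).
#' @examples
#' oat_sensitivity(function(x) x^2, base = 10)
#' # sc_plus 2.2, sc_minus 1.8, sc_mean 2 at +/-20%
#' @export
oat_sensitivity <- function(model, base, delta = 0.20) {
  stopifnot(is.function(model), delta > 0)
  out0 <- model(base)
  outp <- model(base * (1 + delta))
  outm <- model(base * (1 - delta))
  nm <- names(out0)
  if (is.null(nm)) nm <- if (length(out0) == 1) "output" else paste0("output", seq_along(out0))
  undef <- out0 == 0
  sc_plus <- ifelse(undef, NA_real_, ((outp - out0) / out0) / delta)
  sc_minus <- ifelse(undef, NA_real_, ((outm - out0) / out0) / (-delta))
  tibble(
    output = nm,
    sc_plus = unname(sc_plus),
    sc_minus = unname(sc_minus),
    sc_mean = unname((sc_plus + sc_minus) / 2)
  )
}

#' OAT sensitivity over a set of named parameters
#'
#' Applies [oat_sensitivity()] to each parameter of a multi-parameter
#' model, perturbing one at a time while holding the rest at base values.
#'
#' @param model function taking a named numeric vector of parameters and
#'   returning a numeric scalar or named vector of outputs.
#' @param base named numeric vector of base parameter values.
#' @param delta relative perturbation.
#' @return tibble with one row per (parameter, output).
#' @export
oat_sweep <- function(model, base, delta = 0.20) {
  stopifnot(is.function(model), !is.null(names(base)))
  bind_rows(lapply(names(base), function(p) {
    one <- function(x) {
      b <- base
      b[[p]] <- x
      model(b)
    }
    oat_sensitivity(one, base[[p]], delta) |>
      mutate(parameter = p, .before = 1)
  }))
}
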