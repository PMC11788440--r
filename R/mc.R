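#' Monte Carlo propagation of input uncertainty to disease burdens
#'
#' Propagates the influent-concentration and removal-rate distributions of
#' every chemical through the exposure-to-burden chain by Monte Carlo
#' simulation. Per iteration, one source-water concentration is drawn per
#' chemical and SHARED across all evaluated trains (the systems treat the
#' same source water), while removal draws are independent per train and
#' unit. Per-endpoint totals, per-category and per-chemical slices are
#' stored for every iteration, in DALYs person^-1 year^-1.
#'
#' Randomness is organized in named sub-streams derived from `seed` (one
#' per chemical concentration, one per train/unit/chemical removal), so
#' results are reproducible and adding a chemical or unit does not perturb
#' the other draws.
#'
#' @param cecs CEC table (see [read_cec_table()] / [generate_cec_dataset()]).
#' @param trains named list of `treatment_train` objects; a `NULL` element
#'   means untreated source water. Order and names are preserved in the
#'   result.
#' @param ctx an [exposure_context()].
#' @param n_iter number of Monte Carlo iterations (default 10,000).
#' @param seed integer seed driving all sub-streams.
#' @param mixture_mode total aggregation convention, see
#'   [aggregate_mixture()]; category and per-chemical slices are always
#'   additive within their group.
#' @param keep_draws store the sampled inputs (needed by
#'   [mc_sensitivity()]).
#' @return an `mc_run`: a named list of `mc_result` objects, one per
#'   train. Each `mc_result` holds `totals` (per-endpoint numeric vectors
#'   of length `n_iter`), `per_category` and `per_cec` sample matrices,
#'   and (optionally) the input draws.
#' @examples
#' cecs <- generate_cec_dataset(synth_config(seed = 1))$cecs[1:5, ]
#' run <- run_mc(cecs, trains = list(source = NULL), n_iter = 100, seed = 1)
#' mc_summary(run$source)
#' @export
run_mc <- function(cecs, trains = list(source = NULL),
                   ctx = exposure_context(), n_iter = 10000, seed = 1,
                   mixture_mode = "additive", keep_draws = TRUE) {
  if (!is.data.frame(cecs) || nrow(cecs) == 0) {
    stop_usage("`cecs` must be a non-empty CEC table")
  }
  if (n_iter < 1) stop_usage("`n_iter` must be >= 1")
  if (!is.list(trains)) trains <- list(trains)
  if (is.null(names(trains)) || any(names(trains) == "")) {
    names(trains) <- vapply(seq_along(trains), function(i) {
      if (is.null(trains[[i]])) "source" else trains[[i]]$train_id
    }, character(1))
  }

  n_cec <- nrow(cecs)
  ids <- cecs$cec_id

  # shared source-water concentration draws: n_iter x n_cec
  cs_draws <- matrix(0, n_iter, n_cec, dimnames = list(NULL, ids))
  for (i in seq_len(n_cec)) {
    u <- substream_runif(n_iter, seed, paste0("cs/", ids[i]))
    cs_draws[, i] <- q_triangular(u, cecs$conc_low[i], cecs$conc_mode[i],
                                  cecs$conc_high[i])
  }

  results <- lapply(names(trains), function(label) {
    train <- trains[[label]]
    retained <- matrix(1, n_iter, n_cec)
    removal_draws <- list()
    if (!is.null(train)) {
      stopifnot(inherits(train, "treatment_train"))
      for (unit in train$units) {
        idx <- match(ids, unit$removal$cec_id)
        if (anyNA(idx)) {
          stop_usage(sprintf(
            "unit '%s' lacks removal data for: %s (impute first)",
            unit$unit_id,
            paste(head(ids[is.na(idx)], 5), collapse = ", ")
          ))
        }
        r <- matrix(0, n_iter, n_cec)
        for (i in seq_len(n_cec)) {
          u <- substream_runif(
            n_iter, seed,
            paste0("r/", train$train_id, "/", unit$unit_id, "/", ids[i])
          )
          r[, i] <- q_triangular(u, unit$removal$r_low[idx[i]],
                                 unit$removal$r_mode[idx[i]],
                                 unit$removal$r_high[idx[i]])
        }
        retained <- retained * (1 - r)
        if (keep_draws) {
          colnames(r) <- ids
          removal_draws[[unit$unit_id]] <- r
        }
      }
    }
    ce <- cs_draws * retained # residual concentration per iteration

    build_result(label, train, cecs, ce, ctx, n_iter, seed, mixture_mode,
                 draws = if (keep_draws) {
                   list(cs = cs_draws, removals = removal_draws)
                 })
  })
  names(results) <- names(trains)
  structure(results, class = "mc_run")
}

# assemble per-endpoint samples from residual concentrations
build_result <- function(label, train, cecs, ce, ctx, n_iter, seed,
                         mixture_mode, draws = NULL) {
  intake_per_l <- ctx$ir_daily * 365 # L per person-year
  endpoints <- c("cancer", "noncancer")
  totals <- list(); per_category <- list(); per_cec <- list()
  for (ep in endpoints) {
    ef <- if (ep == "cancer") cecs$ef_cancer else cecs$ef_noncancer
    keep <- which(!is.na(ef))
    df <- damage_factor(ctx, ep)
    # annual per-person burden of chemical i: EF*DF*IR_daily*365*CE*1e-12
    # (population and horizon cancel between Eq. 2 and the annualization)
    coef <- ef[keep] * df * intake_per_l * 1e-12
    burden <- sweep(ce[, keep, drop = FALSE], 2, coef, `*`)
    colnames(burden) <- cecs$cec_id[keep]
    per_cec[[ep]] <- burden

    cats <- cecs$category[keep]
    cat_mat <- vapply(unique(cats), function(cc) {
      rowSums(burden[, cats == cc, drop = FALSE])
    }, numeric(n_iter))
    if (is.null(dim(cat_mat))) cat_mat <- matrix(cat_mat, nrow = n_iter,
                                                 dimnames = list(NULL, unique(cats)))
    per_category[[ep]] <- cat_mat

    totals[[ep]] <- switch(mixture_mode,
      additive = rowSums(burden),
      dominant = apply(burden, 1, function(x) if (length(x)) max(x) else 0),
      multiplicative = {
        # independent action on lifetime case probabilities
        p <- sweep(ce[, keep, drop = FALSE], 2,
                   ef[keep] * cumulative_intake(ctx) * 1e-12, `*`)
        if (any(p >= 1)) stop_domain("case probability >= 1; multiplicative mixture undefined")
        p_comb <- 1 - exp(rowSums(log1p(-p)))
        df * p_comb / ctx$years
      },
      stop_usage(sprintf("unknown mixture mode '%s'", mixture_mode))
    )
  }
  structure(
    list(label = label, train_id = if (is.null(train)) NA_character_ else train$train_id,
         n_iter = n_iter, seed = seed, ctx = ctx, mixture_mode = mixture_mode,
         totals = totals, per_category = per_category, per_cec = per_cec,
         draws = draws),
    class = "mc_result"
  )
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result '%s': %d iterations, %s mixture>\n",
              x$label, x$n_iter, x$mixture_mode))
  print(mc_summary(x))
  invisible(x)
}

#' @export
print.mc_run <- function(x, ...) {
  cat(sprintf("<mc_run: %d system(s): %s>\n", length(x),
              paste(names(x), collapse = ", ")))
  for (r in x) print(r)
  invisible(x)
}

#' Empirical cumulative probability distribution function
#'
#' Returns the empirical CDF of a sample as a tibble of sorted values and
#' cumulative probabilities `P(X <= x) = rank / n` (right-continuous step
#' function), the form in which burden distributions are plotted and read
#' against the tolerable-burden threshold.
#'
#' @param samples numeric vector (or an `mc_result` plus `endpoint`).
#' @param endpoint for an `mc_result`, which endpoint's totals to use.
#' @return tibble with columns `value`, `prob`.
#' @export
cpdf <- function(samples, endpoint = c("cancer", "noncancer")) {
  if (inherits(samples, "mc_result")) {
    endpoint <- match.arg(endpoint)
    samples <- samples$totals[[endpoint]]
  }
  if (length(samples) == 0) stop_usage("cpdf needs at least one sample")
  s <- sort(samples)
  tibble(value = s, prob = seq_along(s) / length(s))
}

#' Threshold compliance fraction
#'
#' Percentage of Monte Carlo iterations whose endpoint total lies at or
#' below the tolerable-burden threshold (inclusive comparison).
#'
#' @param mc an `mc_result`.
#' @param endpoint `"cancer"` or `"noncancer"`.
#' @param threshold DALYs person^-1 y^-1; defaults to the context's
#'   threshold (WHO tolerable burden).
#' @return percent in `[0, 100]`.
#' @export
compliance_fraction <- function(mc, endpoint = c("cancer", "noncancer"),
                                threshold = NULL) {
  stopifnot(inherits(mc, "mc_result"))
  endpoint <- match.arg(endpoint)
  if (is.null(threshold)) threshold <- mc$ctx$threshold
  if (threshold < 0) stop_domain("`threshold` must be non-negative")
  100 * mean(mc$totals[[endpoint]] <= threshold)
}

#' Paired system-comparison benefit
#'
#' Per-iteration differences `alt - ref` of endpoint totals between two
#' Monte Carlo results that share the same source-water draws (same seed
#' lineage), and the percentage of iterations in which the alternative
#' system strictly improves on the reference (difference < 0).
#'
#' @param mc_ref,mc_alt `mc_result` objects from the same [run_mc()] call
#'   (same `n_iter` and seed).
#' @param endpoint `"cancer"` or `"noncancer"`.
#' @return a `paired_benefit` list: `differences` (numeric vector),
#'   `benefit_percent`, `endpoint`, labels.
#' @export
paired_benefit <- function(mc_ref, mc_alt, endpoint = c("cancer", "noncancer")) {
  stopifnot(inherits(mc_ref, "mc_result"), inherits(mc_alt, "mc_result"))
  endpoint <- match.arg(endpoint)
  if (mc_ref$n_iter != mc_alt$n_iter) {
    stop_usage("paired comparison requires equal n_iter")
  }
  if (mc_ref$seed != mc_alt$seed) {
    stop_usage("paired comparison requires the same seed lineage (shared source-water draws)")
  }
  d <- mc_alt$totals[[endpoint]] - mc_ref$totals[[endpoint]]
  structure(
    list(differences = d,
         benefit_percent = 100 * mean(d < 0),
         endpoint = endpoint,
         ref = mc_ref$label, alt = mc_alt$label),
    class = "paired_benefit"
  )
}

#' @export
print.paired_benefit <- function(x, ...) {
  cat(sprintf(
    "<paired_benefit %s: '%s' improves on '%s' in %.1f%% of iterations>\n",
    x$endpoint, x$alt, x$ref, x$benefit_percent
  ))
  invisible(x)
}

#' Summary statistics of Monte Carlo burden samples
#'
#' Median, 5th/95th percentiles, mean and 95% percentile interval
#' (2.5th-97.5th) of the simulated burden distribution, at total,
#' category or per-chemical scope. Quantiles use type-7 linear
#' interpolation between order statistics.
#'
#' @param mc an `mc_result`.
#' @param scope `"total"`, `"category"` or `"cec"`.
#' @param endpoint endpoints to include (default both).
#' @return tibble with columns `endpoint`, `group`, `median`, `p5`, `p95`,
#'   `mean`, `ci_lo`, `ci_hi`.
#' @export
mc_summary <- function(mc, scope = c("total", "category", "cec"),
                       endpoint = c("cancer", "noncancer")) {
  stopifnot(inherits(mc, "mc_result"))
  scope <- match.arg(scope)
  endpoint <- match.arg(endpoint, several.ok = TRUE)
  one <- function(x, ep, grp) {
    q <- quantile(x, c(0.05, 0.5, 0.95, 0.025, 0.975), type = 7, names = FALSE)
    tibble(endpoint = ep, group = grp, median = q[2], p5 = q[1], p95 = q[3],
           mean = mean(x), ci_lo = q[4], ci_hi = q[5])
  }
  rows <- list()
  for (ep in endpoint) {
    if (scope == "total") {
      rows[[length(rows) + 1]] <- one(mc$totals[[ep]], ep, "total")
    } else {
      m <- if (scope == "category") mc$per_category[[ep]] else mc$per_cec[[ep]]
      for (g in colnames(m)) {
        rows[[length(rows) + 1]] <- one(m[, g], ep, g)
      }
    }
  }
  bind_rows(rows)
}

#' Repeat-run convergence check
#'
#' Compares the summary statistics (median, p5, p95, mean of each
#' endpoint total) of two Monte Carlo runs of the same configuration under
#' different seeds, reporting the maximum relative deviation. A small
#' deviation indicates the iteration count is adequate for reproducible
#' results.
#'
#' @param run_a,run_b `mc_result` objects with identical configuration but
#'   different seeds.
#' @param tol pass tolerance on the maximum relative deviation
#'   (default 0.05).
#' @return list with `max_rel_dev`, `pass`, and the per-statistic
#'   deviations tibble.
#' @export
convergence_check <- function(run_a, run_b, tol = 0.05) {
  stopifnot(inherits(run_a, "mc_result"), inherits(run_b, "mc_result"))
  if (run_a$seed == run_b$seed) {
    stop_usage("convergence check requires runs with different seeds")
  }
  if (run_a$n_iter != run_b$n_iter) {
    stop_usage("convergence check requires identical configurations")
  }
  sa <- mc_summary(run_a); sb <- mc_summary(run_b)
  stats <- c("median", "p5", "p95", "mean")
  devs <- purrr::map_dfr(stats, function(st) {
    tibble(
      endpoint = sa$endpoint, statistic = st,
      a = sa[[st]], b = sb[[st]],
      rel_dev = abs(sa[[st]] - sb[[st]]) /
        pmax(pmax(abs(sa[[st]]), abs(sb[[st]])), .Machine$double.eps)
    )
  })
  max_dev <- max(devs$rel_dev)
  list(max_rel_dev = max_dev, pass = max_dev <= tol, deviations = devs)
}
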