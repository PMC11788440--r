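#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Monte Carlo burden result
#'
#' Broom-style tidier: one row per endpoint (and group, if `scope` is
#' `"category"` or `"cec"`) with the distribution summaries of the
#' simulated annual per-person burden.
#'
#' @param x an `mc_result`.
#' @param scope `"total"`, `"category"` or `"cec"`.
#' @param ... unused.
#' @return a tibble, see [mc_summary()].
#' @method tidy mc_result
#' @export
tidy.mc_result <- function(x, scope = "total", ...) {
  mc_summary(x, scope = scope)
}

#' One-row overview of a Monte Carlo burden result
#'
#' @param x an `mc_result`.
#' @param ... unused.
#' @return a one-row tibble with the system label, iteration count, seed,
#'   mixture mode, median burdens and threshold-compliance percentages
#'   for both endpoints.
#' @method glance mc_result
#' @export
glance.mc_result <- function(x, ...) {
  tibble(
    system = x$label,
    n_iter = x$n_iter,
    seed = x$seed,
    mixture_mode = x$mixture_mode,
    median_cancer = median(x$totals$cancer),
    median_noncancer = median(x$totals$noncancer),
    compliance_cancer = compliance_fraction(x, "cancer"),
    compliance_noncancer = compliance_fraction(x, "noncancer")
  )
}

#' @rdname tidy.mc_result
#' @method tidy mc_run
#' @export
tidy.mc_run <- function(x, scope = "total", ...) {
  bind_rows(lapply(names(x), function(nm) {
    mutate(mc_summary(x[[nm]], scope = scope), system = nm, .before = 1)
  }))
}

#' @rdname glance.mc_result
#' @method glance mc_run
#' @export
glance.mc_run <- function(x, ...) {
  bind_rows(lapply(unclass(x), glance))
}

#' Tidy a paired system-comparison
#'
#' @param x a `paired_benefit`.
#' @param ... unused.
#' @return one-row tibble with endpoint, labels, benefit percentage and
#'   the median per-iteration difference.
#' @method tidy paired_benefit
#' @export
tidy.paired_benefit <- function(x, ...) {
  tibble(
    endpoint = x$endpoint, reference = x$ref, alternative = x$alt,
    benefit_percent = x$benefit_percent,
    median_difference = median(x$differences)
  )
}
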