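#' @importFrom ggplot2 ggplot aes geom_step geom_vline geom_col geom_hline
#'   labs scale_x_log10 autoplot facet_wrap theme_minimal position_dodge
#' @export
ggplot2::autoplot

#' Plot the cumulative burden distribution of one or more systems
#'
#' Draws the empirical cumulative probability distribution (CPDF) of the
#' annual per-person burden for each system in a run, with a dashed
#' vertical line at the tolerable-burden threshold. Reading a curve at
#' the threshold line gives the compliance fraction.
#'
#' @param object an `mc_run` (or a single `mc_result`).
#' @param endpoint `"cancer"` or `"noncancer"`.
#' @param log_x log-scale the burden axis (default TRUE).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mc_run
#' @export
autoplot.mc_run <- function(object, endpoint = c("cancer", "noncancer"),
                            log_x = TRUE, ...) {
  endpoint <- match.arg(endpoint)
  dat <- bind_rows(lapply(names(object), function(nm) {
    mutate(cpdf(object[[nm]], endpoint), system = nm)
  }))
  thr <- object[[1]]$ctx$threshold
  p <- ggplot(dat, aes(x = .data$value, y = .data$prob, colour = .data$system)) +
    geom_step() +
    geom_vline(xintercept = thr, linetype = "dashed") +
    labs(
      x = bquote("Annual burden (DALYs" ~ person^-1 ~ year^-1 * ")"),
      y = "Cumulative probability",
      title = sprintf("%s disease burden", endpoint),
      colour = "system"
    ) +
    theme_minimal()
  if (log_x) p <- p + scale_x_log10()
  p
}

#' @rdname autoplot.mc_run
#' @method autoplot mc_result
#' @export
autoplot.mc_result <- function(object, endpoint = c("cancer", "noncancer"),
                               log_x = TRUE, ...) {
  run <- structure(setNames(list(object), object$label), class = "mc_run")
  autoplot(run, endpoint = endpoint, log_x = log_x, ...)
}

#' Plot the paired benefit distribution of switching systems
#'
#' CPDF of the per-iteration burden differences (alternative minus
#' reference); mass left of zero is the fraction of simulations in which
#' the alternative system is beneficial.
#'
#' @param object a `paired_benefit`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot paired_benefit
#' @export
autoplot.paired_benefit <- function(object, ...) {
  d <- sort(object$differences)
  dat <- tibble(value = d, prob = seq_along(d) / length(d))
  ggplot(dat, aes(x = .data$value, y = .data$prob)) +
    geom_step() +
    geom_vline(xintercept = 0, linetype = "dashed") +
    labs(
      x = bquote(Delta ~ "burden (DALYs" ~ person^-1 ~ year^-1 * ")"),
      y = "Cumulative probability",
      title = sprintf("%s: '%s' vs '%s' (%.0f%% beneficial)",
                      object$endpoint, object$alt, object$ref,
                      object$benefit_percent)
    ) +
    theme_minimal()
}

#' Bar chart of category contributions to the median burden
#'
#' @param run an `mc_run`.
#' @param endpoint `"cancer"` or `"noncancer"`.
#' @return a ggplot object with one bar group per system, split by
#'   chemical category, with 5th-95th percentile error bars.
#' @export
plot_category_burden <- function(run, endpoint = c("cancer", "noncancer")) {
  stopifnot(inherits(run, "mc_run"))
  endpoint <- match.arg(endpoint)
  dat <- tidy(run, scope = "category") |>
    filter(.data$endpoint == .env$endpoint)
  ggplot(dat, aes(x = .data$system, y = .data$median, fill = .data$group)) +
    geom_col() +
    labs(
      x = NULL,
      y = bquote("Median burden (DALYs" ~ person^-1 ~ year^-1 * ")"),
      fill = "category",
      title = sprintf("Category contributions, %s endpoint", endpoint)
    ) +
    theme_minimal()
}

#' Bar chart of the leading Monte Carlo sensitivities
#'
#' @param sens tibble from [mc_sensitivity()].
#' @param top number of parameters to show.
#' @return a ggplot object.
#' @export
plot_sensitivity <- function(sens, top = 15) {
  dat <- head(sens[order(-abs(sens$rho)), ], top)
  dat$parameter <- factor(dat$parameter, levels = rev(dat$parameter))
  ggplot(dat, aes(x = .data$rho, y = .data$parameter)) +
    geom_col() +
    geom_vline(xintercept = 0) +
    labs(x = "Spearman rank correlation with burden", y = NULL) +
    theme_minimal()
}

#' Bar chart of percent changes across impact categories
#'
#' @param pc tibble from [percent_change()].
#' @return a ggplot object; negative bars are reductions.
#' @export
plot_percent_change <- function(pc) {
  ggplot(pc, aes(x = .data$percent_change, y = .data$category_id)) +
    geom_col() +
    geom_vline(xintercept = 0) +
    labs(x = "Change vs baseline (%)", y = NULL) +
    theme_minimal()
}
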