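#' Uncertainty distribution specifications
#'
#' Every uncertain scalar input (an influent concentration, a per-unit
#' removal fraction) is described by a `dist_spec`: a point value, a
#' triangular distribution, or a uniform distribution, parameterized by
#' `low`, `mode` and `high`. In tabular inputs the same triple appears as
#' three columns (e.g. `conc_low`, `conc_mode`, `conc_high`); a row with
#' `low == mode == high` is a point value.
#'
#' Triangular distributions are the workhorse: when only the mean and the
#' extremes of reported measurements are available, the mean becomes the
#' mode and the extremes the bounds.
#'
#' @param low lower bound.
#' @param mode most likely value (triangular); ignored for `uniform`.
#' @param high upper bound.
#' @param kind one of `"point"`, `"triangular"`, `"uniform"`.
#' @return a `dist_spec` object (a named list with fields `kind`, `low`,
#'   `mode`, `high`).
#' @examples
#' dist_triangular(0, 0.5, 1)
#' dist_point(5)
#' @export
dist_spec <- function(kind, low, mode = low, high = low) {
  kind <- match.arg(kind, c("point", "triangular", "uniform"))
  for (v in list(low = low, mode = mode, high = high)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_usage("dist_spec parameters must be single finite numbers")
    }
  }
  if (kind == "uniform") mode <- (low + high) / 2
  if (kind == "point" && !(low == mode && mode == high)) {
    stop_domain("point distribution requires low = mode = high")
  }
  if (!(low <= mode && mode <= high)) {
    stop_domain(sprintf(
      "invalid distribution: need low <= mode <= high, got (%g, %g, %g)",
      low, mode, high
    ))
  }
  structure(list(kind = kind, low = low, mode = mode, high = high),
            class = "dist_spec")
}

#' @rdname dist_spec
#' @param x point value.
#' @export
dist_point <- function(x) dist_spec("point", x, x, x)

#' @rdname dist_spec
#' @export
dist_triangular <- function(low, mode, high) dist_spec("triangular", low, mode, high)

#' @rdname dist_spec
#' @export
dist_uniform <- function(low, high) dist_spec("uniform", low, high = high)

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec %s (%g, %g, %g)>\n", x$kind, x$low, x$mode, x$high))
  invisible(x)
}

#' Theoretical mean of a distribution specification
#'
#' Point: the value. Triangular: `(low + mode + high) / 3`. Uniform:
#' `(low + high) / 2`. Used for analytic expectations in benchmark
#' ground truths.
#'
#' @param spec a [dist_spec()].
#' @return scalar mean.
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$kind,
    point = spec$low,
    triangular = (spec$low + spec$mode + spec$high) / 3,
    uniform = (spec$low + spec$high) / 2
  )
}

#' Inverse-CDF sampling of distribution specifications
#'
#' Transforms uniform(0, 1) draws into draws from the specified
#' distribution by the inverse cumulative distribution function. For the
#' triangular distribution the piecewise square-root quantile function is
#' used; degenerate widths collapse gracefully to the point value.
#'
#' `sample_dist()` takes a `dist_spec`; `q_triangular()` is the vectorized
#' kernel used internally by the Monte Carlo engine.
#'
#' @param spec a [dist_spec()].
#' @param u numeric vector of probabilities in `[0, 1]`.
#' @return numeric vector of draws, same length as `u`.
#' @examples
#' sample_dist(dist_triangular(0, 0.5, 1), 0.5) # symmetric: 0.5
#' @export
sample_dist <- function(spec, u) {
  stopifnot(inherits(spec, "dist_spec"))
  if (any(u < 0 | u > 1)) stop_domain("u must lie in [0, 1]")
  switch(spec$kind,
    point = rep(spec$low, length(u)),
    uniform = spec$low + u * (spec$high - spec$low),
    triangular = q_triangular(u, spec$low, spec$mode, spec$high)
  )
}

#' @rdname sample_dist
#' @param low,mode,high triangular parameters, scalars or vectors recycled
#'   against `u`.
#' @export
q_triangular <- function(u, low, mode, high) {
  n <- max(length(u), length(low), length(mode), length(high))
  u <- rep_len(u, n); a <- rep_len(low, n)
  c_ <- rep_len(mode, n); b <- rep_len(high, n)
  w <- b - a
  out <- numeric(n)
  degen <- w <= 0
  out[degen] <- a[degen]
  if (any(!degen)) {
    i <- which(!degen)
    fc <- (c_[i] - a[i]) / w[i]
    lower <- u[i] <= fc
    il <- i[lower]; iu <- i[!lower]
    out[il] <- a[il] + sqrt(u[il] * (b[il] - a[il]) * (c_[il] - a[il]))
    out[iu] <- b[iu] - sqrt((1 - u[iu]) * (b[iu] - a[iu]) * (b[iu] - c_[iu]))
  }
  out
}

# Validate a (low, mode, high) column triple from a table; returns a logical
# vector of valid rows or raises with row context.
check_lmh <- function(low, mode, high, what, rows = seq_along(low)) {
  bad <- which(!(low <= mode & mode <= high))
  if (length(bad) > 0) {
    stop_domain(sprintf(
      "%s: need low <= mode <= high, violated at row %s",
      what, paste(rows[bad], collapse = ", ")
    ))
  }
  invisible(TRUE)
}
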