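#' @importFrom rlang abort warn .data .env :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows rename n across all_of pull
#'   distinct row_number
#' @importFrom stats quantile median cor runif setNames
#' @importFrom utils head
NULL

# Polynomial rolling hash of a string modulo the Mersenne prime 2^31 - 1,
# so the result is always a valid R integer seed offset. Exact in doubles:
# intermediates stay below 2^53.
str_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) {
    h <- (h * 1048583 + b) %% 2147483647
  }
  h
}

# Named sub-stream seed: mixes a base seed with a stream label so that each
# artifact / chemical / unit gets its own reproducible stream and adding a
# new stream never perturbs existing ones.
substream_seed <- function(seed, label) {
  as.integer((as.numeric(seed) + str_hash(label)) %% 2147483647)
}

# Draw n uniforms from a named sub-stream without disturbing the caller's RNG.
substream_runif <- function(n, seed, label) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, label))
  runif(n)
}

stop_domain <- function(msg, class = "dwburden_domain_error") {
  abort(msg, class = c(class, "dwburden_error"))
}

stop_usage <- function(msg, class = "dwburden_usage_error") {
  abort(msg, class = c(class, "dwburden_error"))
}

check_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_usage(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_min && x <= min) {
    stop_domain(sprintf("`%s` must be > %g (got %g)", name, min, x))
  }
  if (!strict_min && x < min) {
    stop_domain(sprintf("`%s` must be >= %g (got %g)", name, min, x))
  }
  invisible(x)
}

cec_categories <- function() {
  c("pesticide", "industrial", "pharmaceutical", "antibiotic", "DBP", "PCP")
}
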