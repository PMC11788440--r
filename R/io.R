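#' Read a chemical (CEC) table
#'
#' Reads the comma-delimited chemical table with columns `cec_id`, `name`,
#' `category`, `conc_low`, `conc_mode`, `conc_high`, `lod`, `loq`,
#' `ef_cancer`, `ef_noncancer` (concentrations and limits in ng/L, effect
#' factors in cases/kg; blank cells mean absent). Validates categories,
#' ordering of the concentration triple and non-negativity, and applies
#' the half-of-limit censoring rule: rows whose concentration cells are
#' all blank but that carry a detection (LOD) or quantification (LOQ)
#' limit are assigned the point concentration `0.5 * limit`, with LOD
#' taking precedence.
#'
#' @param path CSV file path.
#' @param quiet suppress the per-category count message.
#' @return a tibble, one row per chemical, with a logical `censored`
#'   column marking rows that were imputed from a detection limit.
#' @export
read_cec_table <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop_usage(sprintf("file not found: %s", path))
  spec <- readr::cols(
    cec_id = readr::col_character(),
    name = readr::col_character(),
    category = readr::col_character(),
    conc_low = readr::col_double(),
    conc_mode = readr::col_double(),
    conc_high = readr::col_double(),
    lod = readr::col_double(),
    loq = readr::col_double(),
    ef_cancer = readr::col_double(),
    ef_noncancer = readr::col_double()
  )
  tbl <- readr::read_csv(path, col_types = spec)
  missing_cols <- setdiff(names(spec$cols), names(tbl))
  if (length(missing_cols) > 0) {
    stop_usage(sprintf("cec table missing columns: %s",
                       paste(missing_cols, collapse = ", ")))
  }
  validate_cec_table(tbl)
}

validate_cec_table <- function(tbl) {
  if (anyDuplicated(tbl$cec_id)) stop_domain("cec ids must be unique")
  bad_cat <- which(!tbl$category %in% cec_categories())
  if (length(bad_cat) > 0) {
    stop_domain(sprintf("unknown category '%s' at row %d",
                        tbl$category[bad_cat[1]], bad_cat[1]))
  }

  # censoring: blank concentration triple + a limit -> point at half limit
  censored <- is.na(tbl$conc_mode) & is.na(tbl$conc_low) & is.na(tbl$conc_high)
  if (any(censored)) {
    limit <- ifelse(!is.na(tbl$lod), tbl$lod, tbl$loq)
    no_limit <- which(censored & is.na(limit))
    if (length(no_limit) > 0) {
      stop_domain(sprintf(
        "row %d: below-limit concentration but no LOD or LOQ given",
        no_limit[1]
      ))
    }
    half <- apply_censoring(rep(NA_real_, sum(censored)), limit[censored])
    tbl$conc_low[censored] <- half
    tbl$conc_mode[censored] <- half
    tbl$conc_high[censored] <- half
  }
  tbl$censored <- censored

  if (any(is.na(tbl$conc_mode))) {
    stop_domain(sprintf("row %d: incomplete concentration triple",
                        which(is.na(tbl$conc_mode))[1]))
  }
  neg <- which(tbl$conc_low < 0)
  if (length(neg) > 0) {
    stop_domain(sprintf("negative concentration at row %d", neg[1]))
  }
  check_lmh(tbl$conc_low, tbl$conc_mode, tbl$conc_high, "cec table")
  ef_neg <- which(tbl$ef_cancer < 0 | tbl$ef_noncancer < 0)
  if (length(ef_neg) > 0) {
    stop_domain(sprintf("negative effect factor at row %d", ef_neg[1]))
  }
  no_ef <- is.na(tbl$ef_cancer) & is.na(tbl$ef_noncancer)
  if (any(no_ef)) {
    warn(sprintf("%d chemical(s) have no effect factor for either endpoint and are inert in burden analysis",
                 sum(no_ef)))
  }
  as_tibble(tbl)
}

#' Half-of-limit censoring rule
#'
#' Concentrations reported below a detection (LOD) or quantification (LOQ)
#' limit are conservatively assigned half the limit; detected values pass
#' through unchanged. Idempotent: applying it twice changes nothing.
#'
#' @param value numeric vector; `NA` marks a below-limit entry.
#' @param limit the applicable LOD or LOQ (ng/L), recycled against `value`.
#' @return numeric vector with below-limit entries replaced by
#'   `0.5 * limit`.
#' @examples
#' apply_censoring(c(NA, 7.3), 10) # 5.0, 7.3
#' @export
apply_censoring <- function(value, limit) {
  n <- max(length(value), length(limit))
  value <- rep_len(value, n); limit <- rep_len(limit, n)
  need <- is.na(value)
  if (any(need & (is.na(limit) | limit <= 0))) {
    stop_domain("below-limit value with missing or non-positive limit")
  }
  ifelse(need, 0.5 * limit, value)
}

#' Read a removal-rate table
#'
#' Long-format CSV with columns `train_id`, `unit_id`, `cec_id`, `r_low`,
#' `r_mode`, `r_high` (dimensionless fractions). Fractions are validated
#' to lie in `[0, 1]` — out-of-range data raise an error rather than being
#' clipped.
#'
#' @param path CSV file path.
#' @return a tibble.
#' @export
read_removal_table <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("file not found: %s", path))
  tbl <- readr::read_csv(path, col_types = readr::cols(
    train_id = readr::col_character(),
    unit_id = readr::col_character(),
    cec_id = readr::col_character(),
    r_low = readr::col_double(),
    r_mode = readr::col_double(),
    r_high = readr::col_double()
  ))
  if (anyDuplicated(tbl[c("train_id", "unit_id", "cec_id")])) {
    stop_domain("duplicate (train, unit, chemical) removal rows")
  }
  validate_removal_values(tbl)
  as_tibble(tbl)
}

#' Read / write train definitions and exposure contexts (JSON)
#'
#' `read_train_def()` reads `{train_id, units: [{unit_id, name}, ...]}`
#' preserving unit order; `read_context()` reads the exposure-context
#' constants. The `write_*` counterparts serialize the same schemas.
#'
#' @param path JSON file path.
#' @return `read_train_def()`: a list with `train_id` and a `units`
#'   tibble; `read_context()`: an [exposure_context()].
#' @export
read_train_def <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$train_id) || is.null(x$units)) {
    stop_usage("train definition must contain train_id and units")
  }
  list(train_id = x$train_id, units = as_tibble(x$units))
}

#' @rdname read_train_def
#' @export
read_context <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  exposure_context(
    sp = x$sp, ir_daily = x$ir_daily, years = x$years,
    df_cancer = x$df_cancer, df_noncancer = x$df_noncancer,
    threshold = x$threshold
  )
}

#' @rdname read_train_def
#' @param train_def list with `train_id` and `units` tibble.
#' @export
write_train_def <- function(train_def, path) {
  jsonlite::write_json(
    list(train_id = train_def$train_id,
         units = train_def$units[, c("unit_id", "name")]),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname read_train_def
#' @param ctx an [exposure_context()].
#' @export
write_context <- function(ctx, path) {
  stopifnot(inherits(ctx, "exposure_context"))
  jsonlite::write_json(unclass(ctx), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write chemical / removal tables
#'
#' CSV writers for the two tabular schemas, inverse of [read_cec_table()]
#' and [read_removal_table()]. Values round-trip bit-exactly for decimal
#' text of up to 15 significant digits.
#'
#' @param tbl the table to write.
#' @param path destination CSV path.
#' @export
write_cec_table <- function(tbl, path) {
  cols <- c("cec_id", "name", "category", "conc_low", "conc_mode",
            "conc_high", "lod", "loq", "ef_cancer", "ef_noncancer")
  readr::write_csv(tbl[, cols], path)
  invisible(path)
}

#' @rdname write_cec_table
#' @export
write_removal_table <- function(tbl, path) {
  cols <- c("train_id", "unit_id", "cec_id", "r_low", "r_mode", "r_high")
  readr::write_csv(tbl[, cols], path)
  invisible(path)
}

# --- imputation -------------------------------------------------------------

#' Category-mean imputation of missing removal rates
#'
#' When a unit process has no removal data for a chemical, the missing
#' triple is imputed as the element-wise mean of the (low, mode, high)
#' parameters across same-category chemicals that do have data in that
#' unit. `impute_removal()` imputes one (unit, chemical) pair;
#' `complete_removal_table()` fills every missing pair for a train and
#' flags imputed rows.
#'
#' @param removal_table long removal tibble (see [read_removal_table()]),
#'   already filtered or carrying a `train_id` column.
#' @param unit_id,cec_id the pair to impute.
#' @param cecs CEC table providing the category of each chemical.
#' @return `impute_removal()`: a one-row tibble `r_low`, `r_mode`,
#'   `r_high`; `complete_removal_table()`: the completed removal tibble
#'   with an `imputed` flag.
#' @export
impute_removal <- function(removal_table, unit_id, cec_id, cecs) {
  cat_i <- cecs$category[match(cec_id, cecs$cec_id)]
  if (is.na(cat_i)) stop_usage(sprintf("unknown chemical '%s'", cec_id))
  peers <- cecs$cec_id[cecs$category == cat_i & cecs$cec_id != cec_id]
  donor <- removal_table |>
    filter(.data$unit_id == .env$unit_id, .data$cec_id %in% peers)
  if (nrow(donor) == 0) {
    stop_domain(sprintf(
      "cannot impute removal for unit '%s': no %s chemical has data there",
      unit_id, cat_i
    ))
  }
  tibble(
    r_low = mean(donor$r_low),
    r_mode = mean(donor$r_mode),
    r_high = mean(donor$r_high)
  )
}

#' @rdname impute_removal
#' @param train_def list with `train_id` and ordered `units` tibble.
#' @export
complete_removal_table <- function(removal_table, train_def, cecs) {
  tid <- train_def$train_id
  if ("train_id" %in% names(removal_table)) {
    removal_table <- filter(removal_table, .data$train_id == tid)
  }
  full <- tidyr::expand_grid(unit_id = train_def$units$unit_id,
                             cec_id = cecs$cec_id)
  have <- removal_table |> select(all_of(c("unit_id", "cec_id", "r_low", "r_mode", "r_high")))
  merged <- left_join(full, have, by = c("unit_id", "cec_id"))
  merged$imputed <- is.na(merged$r_mode)
  miss <- which(merged$imputed)
  for (i in miss) {
    fill <- impute_removal(have, merged$unit_id[i], merged$cec_id[i], cecs)
    merged$r_low[i] <- fill$r_low
    merged$r_mode[i] <- fill$r_mode
    merged$r_high[i] <- fill$r_high
  }
  merged$train_id <- tid
  merged[, c("train_id", "unit_id", "cec_id", "r_low", "r_mode", "r_high", "imputed")]
}

#' Load a complete, simulation-ready treatment train
#'
#' Convenience wrapper: reads a train definition and removal table,
#' imputes missing removal entries by category means, and assembles the
#' `treatment_train` object.
#'
#' @param train_def list from [read_train_def()] (or built in code).
#' @param removal_table tibble from [read_removal_table()].
#' @param cecs CEC table.
#' @return a `treatment_train`.
#' @export
assemble_train <- function(train_def, removal_table, cecs) {
  completed <- complete_removal_table(removal_table, train_def, cecs)
  make_train(train_def$train_id, train_def$units, completed)
}
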