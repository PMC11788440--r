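#' Treatment trains
#'
#' A treatment train is an ordered list of unit processes; each unit holds
#' per-chemical removal-rate distributions as a tibble with columns
#' `cec_id`, `r_low`, `r_mode`, `r_high` (fractions in `[0, 1]`) and an
#' `imputed` flag. `make_train()` assembles one from a train definition
#' (ordered unit ids and names) and a long removal table.
#'
#' @param train_id identifier, e.g. `"rbf_ro"`.
#' @param units tibble with columns `unit_id`, `name` in process order.
#' @param removal_table tibble with columns `unit_id`, `cec_id`, `r_low`,
#'   `r_mode`, `r_high` (a `train_id` column, if present, is filtered to
#'   `train_id`).
#' @return a `treatment_train` object.
#' @export
make_train <- function(train_id, units, removal_table) {
  stopifnot(is.data.frame(units), all(c("unit_id", "name") %in% names(units)))
  if (anyDuplicated(units$unit_id)) stop_domain("unit ids must be unique")
  if ("train_id" %in% names(removal_table)) {
    removal_table <- filter(removal_table, .data$train_id == .env$train_id)
  }
  validate_removal_values(removal_table)
  if (!"imputed" %in% names(removal_table)) removal_table$imputed <- FALSE
  unit_list <- lapply(seq_len(nrow(units)), function(i) {
    uid <- units$unit_id[i]
    rem <- removal_table |>
      filter(.data$unit_id == uid) |>
      select(all_of(c("cec_id", "r_low", "r_mode", "r_high", "imputed")))
    if (anyDuplicated(rem$cec_id)) {
      stop_domain(sprintf("duplicate (unit, chemical) removal rows in unit '%s'", uid))
    }
    list(unit_id = uid, name = units$name[i], removal = rem)
  })
  names(unit_list) <- units$unit_id
  structure(list(train_id = train_id, units = unit_list),
            class = "treatment_train")
}

validate_removal_values <- function(removal_table) {
  req <- c("unit_id", "cec_id", "r_low", "r_mode", "r_high")
  if (!all(req %in% names(removal_table))) {
    stop_usage(sprintf("removal table must have columns %s",
                       paste(req, collapse = ", ")))
  }
  with(removal_table, {
    bad <- which(r_low < 0 | r_high > 1)
    if (length(bad) > 0) {
      stop_domain(sprintf(
        "removal fractions outside [0, 1] at row %s (unit %s)",
        paste(head(bad, 5), collapse = ", "),
        paste(unique(unit_id[head(bad, 5)]), collapse = ", ")
      ))
    }
    check_lmh(r_low, r_mode, r_high, "removal table")
  })
  invisible(removal_table)
}

#' @export
print.treatment_train <- function(x, ...) {
  cat(sprintf("<treatment_train '%s': %d units>\n", x$train_id, length(x$units)))
  for (u in x$units) {
    cat(sprintf("  %-22s %3d chemicals (%d imputed)\n",
                u$unit_id, nrow(u$removal), sum(u$removal$imputed)))
  }
  invisible(x)
}

#' Number of units in a train
#' @param train a `treatment_train`.
#' @return integer count of unit processes.
#' @export
n_units <- function(train) {
  stopifnot(inherits(train, "treatment_train"))
  length(train$units)
}
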