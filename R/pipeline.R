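#' Pipeline front end: generate, simulate, analyse, report
#'
#' These functions tie the modules into a file-based workflow suitable for
#' scripted use (a thin command-line wrapper over them ships in
#' `inst/cli/wealth.R`). All randomness flows from a single integer seed;
#' repeating any command with the same seed reproduces its outputs
#' byte-identically. Logs go to `stderr`; results are written as CSV/JSON
#' under the output directory, never interleaved with logs.
#'
#' @name pipeline
NULL

log_msg <- function(...) message(sprintf(...))

#' Generate synthetic input bundles on disk
#'
#' Presets: `"paperlike"` writes the 93-chemical table, the two-train
#' removal table, both train definitions and the default exposure context;
#' `"benchmark"` writes the planted-dominance two-system scenario with its
#' analytic ground truth; `"lci"` writes the synthetic life-cycle fixture
#' (inventories, characterization factors, electricity mixes). A
#' `manifest.json` with the seed and MD5 checksums of every written file
#' is placed alongside.
#'
#' @param out_dir output directory (created if needed).
#' @param preset one of `"paperlike"`, `"benchmark"`, `"lci"`.
#' @param seed integer seed.
#' @return (invisibly) the manifest as a list.
#' @export
wealth_generate <- function(out_dir, preset = c("paperlike", "benchmark", "lci"),
                            seed = 1) {
  preset <- match.arg(preset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  w <- function(name) file.path(out_dir, name)

  if (preset == "paperlike") {
    ds <- generate_cec_dataset(synth_config(seed = seed))
    write_cec_table(ds$cecs_raw, w("cec_table.csv"))
    write_removal_table(ds$removals, w("removal_table.csv"))
    write_train_def(ds$train_defs$rbf_ro, w("train_rbf_ro.json"))
    write_train_def(ds$train_defs$rbf_et, w("train_rbf_et.json"))
    write_context(exposure_context(), w("context.json"))
    written <- c("cec_table.csv", "removal_table.csv", "train_rbf_ro.json",
                 "train_rbf_et.json", "context.json")
    log_msg("generated %d chemicals, %d removal rows", nrow(ds$cecs), nrow(ds$removals))
  } else if (preset == "benchmark") {
    bm <- generate_two_system_benchmark(seed = seed)
    write_cec_table(bm$cecs, w("cec_table.csv"))
    rem <- bind_rows(lapply(bm$trains, function(tr) {
      bind_rows(lapply(tr$units, function(u) {
        mutate(u$removal, train_id = tr$train_id, unit_id = u$unit_id)
      }))
    }))
    write_removal_table(rem, w("removal_table.csv"))
    for (tr in bm$trains) {
      def <- list(train_id = tr$train_id,
                  units = tibble(unit_id = names(tr$units),
                                 name = names(tr$units)))
      write_train_def(def, w(sprintf("train_%s.json", tr$train_id)))
    }
    write_context(bm$ctx, w("context.json"))
    readr::write_csv(bm$ground_truth, w("ground_truth.csv"))
    written <- c("cec_table.csv", "removal_table.csv", "train_conventional.json",
                 "train_membrane.json", "context.json", "ground_truth.csv")
  } else {
    fx <- generate_lci_fixture(seed = seed)
    for (nm in names(fx$inventories)) {
      readr::write_csv(fx$inventories[[nm]], w(sprintf("inventory_%s.csv", nm)))
      written <- c(written, sprintf("inventory_%s.csv", nm))
    }
    readr::write_csv(fx$factors, w("factors.csv"))
    readr::write_csv(fx$mixes, w("mixes.csv"))
    written <- c(written, "factors.csv", "mixes.csv")
  }

  manifest <- list(
    preset = preset, seed = seed,
    files = as.list(tools::md5sum(file.path(out_dir, written)))
  )
  names(manifest$files) <- written
  jsonlite::write_json(manifest, w("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}

#' Run the Monte Carlo burden simulation from files on disk
#'
#' Loads the chemical table, removal table, train definitions and
#' exposure context, assembles imputation-completed trains, runs the
#' Monte Carlo engine for the untreated source water plus every train
#' (shared source-water draws), and writes per-iteration samples
#' (`samples.csv`), summary statistics, compliance fractions, CPDF points
#' and — when at least two trains are given — the paired benefit analysis
#' to the run directory, together with a `run_config.json` that makes the
#' run reproducible.
#'
#' @param cec_file,removal_file CSV inputs (schemas of [read_cec_table()]
#'   and [read_removal_table()]).
#' @param train_files character vector of train-definition JSON paths.
#' @param context_file optional context JSON; defaults to
#'   [exposure_context()] defaults.
#' @param out_dir run directory.
#' @param iterations,seed,mixture_mode passed to [run_mc()].
#' @param include_source also simulate untreated source water.
#' @return (invisibly) the `mc_run`.
#' @export
wealth_simulate <- function(cec_file, removal_file, train_files,
                            out_dir, context_file = NULL,
                            iterations = 10000, seed = 1,
                            mixture_mode = "additive",
                            include_source = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cecs <- read_cec_table(cec_file)
  removals <- read_removal_table(removal_file)
  ctx <- if (is.null(context_file)) exposure_context() else read_context(context_file)
  defs <- lapply(train_files, read_train_def)
  trains <- lapply(defs, assemble_train, removal_table = removals, cecs = cecs)
  names(trains) <- vapply(defs, `[[`, character(1), "train_id")
  all_trains <- if (include_source) c(list(source = NULL), trains) else trains

  run <- run_mc(cecs, all_trains, ctx = ctx, n_iter = iterations,
                seed = seed, mixture_mode = mixture_mode)

  samples <- bind_rows(lapply(names(run), function(nm) {
    tibble(system = nm, iteration = seq_len(run[[nm]]$n_iter),
           cancer = run[[nm]]$totals$cancer,
           noncancer = run[[nm]]$totals$noncancer)
  }))
  readr::write_csv(samples, file.path(out_dir, "samples.csv"))
  readr::write_csv(tidy(run, scope = "total"),
                   file.path(out_dir, "summary_total.csv"))
  readr::write_csv(tidy(run, scope = "category"),
                   file.path(out_dir, "summary_category.csv"))

  cpdf_pts <- bind_rows(lapply(names(run), function(nm) {
    bind_rows(
      mutate(cpdf(run[[nm]], "cancer"), endpoint = "cancer", system = nm),
      mutate(cpdf(run[[nm]], "noncancer"), endpoint = "noncancer", system = nm)
    )
  }))
  readr::write_csv(cpdf_pts, file.path(out_dir, "cpdf.csv"))

  summary_json <- list(
    systems = lapply(setNames(names(run), names(run)), function(nm) {
      g <- glance(run[[nm]])
      as.list(g)
    })
  )
  if (length(trains) >= 2) {
    nms <- names(trains)
    benefits <- list()
    for (ep in c("cancer", "noncancer")) {
      pb <- paired_benefit(run[[nms[1]]], run[[nms[2]]], ep)
      benefits[[ep]] <- list(
        reference = pb$ref, alternative = pb$alt,
        benefit_percent = pb$benefit_percent,
        median_difference = median(pb$differences)
      )
    }
    summary_json$paired_benefit <- benefits
  }
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  config <- list(
    cec_file = cec_file, removal_file = removal_file,
    train_files = as.list(train_files),
    context_file = context_file, iterations = iterations, seed = seed,
    mixture_mode = mixture_mode, include_source = include_source
  )
  jsonlite::write_json(config, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  log_msg("simulated %d systems x %d iterations", length(run), iterations)
  invisible(run)
}

#' Sensitivity analysis for a completed run directory
#'
#' Re-executes the Monte Carlo run recorded in `run_config.json`
#' (deterministic given its seed), keeping the input draws, and writes
#' Spearman rank-correlation sensitivities of every influent
#' concentration and removal draw against both endpoint totals for each
#' treated system.
#'
#' @param run_dir directory written by [wealth_simulate()].
#' @return (invisibly) the combined sensitivity tibble.
#' @export
wealth_sensitivity <- function(run_dir) {
  cfg_path <- file.path(run_dir, "run_config.json")
  if (!file.exists(cfg_path)) {
    stop_usage(sprintf("not a run directory (missing run_config.json): %s", run_dir))
  }
  cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  run <- wealth_simulate(
    cec_file = cfg$cec_file, removal_file = cfg$removal_file,
    train_files = unlist(cfg$train_files), out_dir = tempfile("resim"),
    context_file = cfg$context_file, iterations = cfg$iterations,
    seed = cfg$seed, mixture_mode = cfg$mixture_mode,
    include_source = cfg$include_source
  )
  out <- bind_rows(lapply(names(run), function(nm) {
    bind_rows(lapply(c("cancer", "noncancer"), function(ep) {
      mutate(mc_sensitivity(run[[nm]], ep), endpoint = ep, system = nm,
             .before = 1)
    }))
  }))
  readr::write_csv(out, file.path(run_dir, "sensitivity.csv"))
  invisible(out)
}

#' Characterize inventories and scenarios from files on disk
#'
#' Loads inventory, factor and (optionally) mix tables, characterizes each
#' inventory — optionally after electricity-mix resolution and a
#' mitigation scenario — and writes `impacts.csv` plus, when two
#' inventories are given, `percent_change.csv` (second vs first).
#'
#' @param inventory_files named character vector of inventory CSV paths.
#' @param factors_file characterization-factor CSV.
#' @param out_dir output directory.
#' @param mixes_file,country optional electricity-mix CSV and country id.
#' @param scenario optional [scenario_spec()].
#' @return (invisibly) the impacts tibble.
#' @export
wealth_lca <- function(inventory_files, factors_file, out_dir,
                       mixes_file = NULL, country = NULL, scenario = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  factors <- readr::read_csv(factors_file, col_types = readr::cols())
  mix <- NULL
  if (!is.null(mixes_file) && !is.null(country)) {
    mixes <- readr::read_csv(mixes_file, col_types = readr::cols())
    mix <- filter(mixes, .data$country_id == country)
    if (nrow(mix) == 0) stop_usage(sprintf("no mix for country '%s'", country))
  }
  if (is.null(names(inventory_files))) {
    names(inventory_files) <- tools::file_path_sans_ext(basename(inventory_files))
  }
  impacts <- bind_rows(lapply(names(inventory_files), function(nm) {
    inv <- readr::read_csv(inventory_files[[nm]], col_types = readr::cols())
    if (!is.null(scenario)) inv <- apply_scenario(inv, scenario)
    if (!is.null(mix)) inv <- apply_electricity_mix(inv, mix)
    mutate(characterize(inv, factors), system = nm, .before = 1)
  }))
  readr::write_csv(impacts, file.path(out_dir, "impacts.csv"))
  if (length(inventory_files) >= 2) {
    nms <- names(inventory_files)
    base <- filter(impacts, .data$system == nms[1]) |> select(-"system")
    alt <- filter(impacts, .data$system == nms[2]) |> select(-"system")
    readr::write_csv(percent_change(base, alt),
                     file.path(out_dir, "percent_change.csv"))
  }
  invisible(impacts)
}

#' Assemble a human-readable report for a run directory
#'
#' Writes `report.txt`: per-system medians with 5th/95th percentiles by
#' endpoint and category, threshold compliance against the tolerable
#' burden, paired benefit fractions, and (if present) the leading
#' sensitivity rankings. Regeneration over the same run directory is
#' byte-identical.
#'
#' @param run_dir directory written by [wealth_simulate()].
#' @return (invisibly) the report path.
#' @export
wealth_report <- function(run_dir) {
  need <- c("summary_total.csv", "summary_category.csv", "summary.json")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing) > 0) {
    stop_usage(sprintf("incomplete run directory, missing: %s",
                       paste(missing, collapse = ", ")))
  }
  tot <- readr::read_csv(file.path(run_dir, "summary_total.csv"),
                         col_types = readr::cols())
  cat_s <- readr::read_csv(file.path(run_dir, "summary_category.csv"),
                           col_types = readr::cols())
  sj <- jsonlite::read_json(file.path(run_dir, "summary.json"),
                            simplifyVector = TRUE)

  lines <- c("Disease-burden simulation report",
             "================================", "")
  for (nm in names(sj$systems)) {
    s <- sj$systems[[nm]]
    lines <- c(lines, sprintf("System '%s' (%s iterations, seed %s):",
                              nm, format(s$n_iter), format(s$seed)))
    for (ep in c("cancer", "noncancer")) {
      row <- tot[tot$system == nm & tot$endpoint == ep, ]
      comp <- if (ep == "cancer") s$compliance_cancer else s$compliance_noncancer
      lines <- c(lines, sprintf(
        "  %-9s median %.3e (p5 %.3e, p95 %.3e) DALYs/person/y; %.1f%% of iterations within the tolerable burden%s",
        ep, row$median, row$p5, row$p95, comp,
        if (comp == 100) " (threshold met in all iterations)" else ""
      ))
    }
    sub <- cat_s[cat_s$system == nm, ]
    for (ep in unique(sub$endpoint)) {
      eps <- sub[sub$endpoint == ep & sub$median > 0, ]
      eps <- eps[order(-eps$median), ]
      if (nrow(eps) == 0) next
      lines <- c(lines, sprintf("  leading %s categories: %s", ep,
                                paste(sprintf("%s (%.2e)", eps$group,
                                              eps$median)[seq_len(min(3, nrow(eps)))],
                                      collapse = ", ")))
    }
    lines <- c(lines, "")
  }
  if (!is.null(sj$paired_benefit)) {
    lines <- c(lines, "Paired system comparison:")
    for (ep in names(sj$paired_benefit)) {
      b <- sj$paired_benefit[[ep]]
      lines <- c(lines, sprintf(
        "  %s: switching '%s' -> '%s' is beneficial in %.1f%% of iterations (median difference %.3e)",
        ep, b$reference, b$alternative, b$benefit_percent, b$median_difference
      ))
    }
    lines <- c(lines, "")
  }
  sens_path <- file.path(run_dir, "sensitivity.csv")
  if (file.exists(sens_path)) {
    sens <- readr::read_csv(sens_path, col_types = readr::cols())
    lines <- c(lines, "Top sensitivities (|Spearman rho|):")
    top <- head(sens[order(-abs(sens$rho)), ], 5)
    lines <- c(lines, sprintf("  %s / %s: %s rho = %.3f",
                              top$system, top$endpoint, top$parameter, top$rho))
  }
  out <- file.path(run_dir, "report.txt")
  writeLines(lines, out)
  invisible(out)
}
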