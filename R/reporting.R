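warn_placeholders <- function(cfg) {
  flat <- flatten_config(cfg)
  nfp <- flat$parameter[flat$provenance == "not from paper" & !is.na(flat$provenance)]
  if (length(nfp) > 0) {
    warning("placeholder parameters in use (not sourced from the publication): ",
            paste(unique(nfp), collapse = ", "), call. = FALSE)
  }
  invisible(nfp)
}

#' Write a JSON summary of net-benefit series
#'
#' One entry per scenario with the cumulative discounted cost, benefit, and
#' net benefit at full precision, display-rounded variants in millions of USD
#' to one decimal place, and the acute/chronic shares of the benefit.
#'
#' @param series_list List of `net_benefit_series` objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(series_list, path) {
  stopifnot(length(series_list) >= 1)
  entries <- lapply(series_list, function(s) {
    tot <- net_benefit_totals(s)
    list(
      scenario = tot$scenario,
      cost_usd = tot$cost,
      benefit_usd = tot$benefit,
      net_benefit_usd = tot$net_benefit,
      cost_musd = round(tot$cost / 1e6, 1),
      benefit_musd = round(tot$benefit / 1e6, 1),
      net_benefit_musd = round(tot$net_benefit / 1e6, 1),
      benefit_share_acute = tot$share_acute,
      benefit_share_chronic = tot$share_chronic
    )
  })
  names(entries) <- vapply(entries, `[[`, character(1), "scenario")
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

run_manifest <- function(cfg_path, scenario_names, horizon, outputs) {
  list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("saltsim")),
    scenarios = scenario_names,
    horizon_years = horizon,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  )
}

#' Run the full simulation pipeline and write its artifacts
#'
#' Loads (or takes) a configuration, runs the null trajectory and every
#' requested scenario, and writes per-scenario trajectory and net-benefit
#' CSVs, a JSON summary, a copy of the configuration in use, and a run
#' manifest with the configuration checksum. Placeholder parameters (those
#' with provenance "not from paper") trigger a warning on every run.
#'
#' @param config A `salt_config`, a path to a YAML config file, or `NULL`
#'   for [baseline_config()].
#' @param scenarios Character vector of scenario names (default: all).
#' @param out_dir Output directory (created if missing).
#' @return Named list of written file paths, invisibly.
#' @export
run_pipeline <- function(config = NULL, scenarios = NULL, out_dir = ".") {
  cfg <- if (is.null(config)) baseline_config()
    else if (is.character(config)) load_config(config)
    else config
  assert_valid_config(cfg)
  if (is.null(scenarios)) scenarios <- names(cfg$scenarios)
  unknown <- setdiff(scenarios, names(cfg$scenarios))
  if (length(unknown) > 0) {
    stop("unknown scenario(s) ", paste(unknown, collapse = ", "),
         "; known scenarios: ", paste(names(cfg$scenarios), collapse = ", "),
         call. = FALSE)
  }
  warn_placeholders(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg_path <- file.path(out_dir, "config_used.yaml")
  write_config(cfg, cfg_path)

  outputs <- list(config = cfg_path)
  null_traj <- run_cohort(cfg, NULL)
  p <- file.path(out_dir, "trajectory_null.csv")
  utils::write.csv(as.data.frame(null_traj), p, row.names = FALSE)
  outputs$trajectory_null <- p

  series_list <- list()
  for (nm in scenarios) {
    traj <- run_cohort(cfg, nm)
    p <- file.path(out_dir, paste0("trajectory_", nm, ".csv"))
    utils::write.csv(as.data.frame(traj), p, row.names = FALSE)
    outputs[[paste0("trajectory_", nm)]] <- p

    nb <- cumulative_net_benefit(cfg, nm)
    p <- file.path(out_dir, paste0("net_benefit_", nm, ".csv"))
    utils::write.csv(as.data.frame(nb), p, row.names = FALSE)
    outputs[[paste0("net_benefit_", nm)]] <- p
    series_list[[nm]] <- nb
  }

  p <- file.path(out_dir, "summary.json")
  write_summary(series_list, p)
  outputs$summary <- p

  manifest <- run_manifest(cfg_path, scenarios, as.integer(cfg$horizon_years),
                           outputs)
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE)
  outputs$manifest <- p
  invisible(outputs)
}

#' Run the one-way sensitivity pipeline and write the tornado table
#'
#' @inheritParams run_pipeline
#' @param scenario Single scenario name.
#' @param specs List of [sweep_spec()]s; default [default_sweep_specs()].
#' @return Path of the written tornado CSV, invisibly.
#' @export
sensitivity_pipeline <- function(config = NULL, scenario, out_dir = ".",
                                 specs = NULL) {
  cfg <- if (is.null(config)) baseline_config()
    else if (is.character(config)) load_config(config)
    else config
  assert_valid_config(cfg)
  if (!scenario %in% names(cfg$scenarios)) {
    stop("unknown scenario '", scenario, "'; known scenarios: ",
         paste(names(cfg$scenarios), collapse = ", "), call. = FALSE)
  }
  if (is.null(specs)) specs <- default_sweep_specs(cfg, scenario)
  if (length(specs) == 0) stop("no sweep specs", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- tornado(cfg, scenario, specs)
  p <- file.path(out_dir, paste0("tornado_", scenario, ".csv"))
  utils::write.csv(tab, p, row.names = FALSE)
  invisible(p)
}
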