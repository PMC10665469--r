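#' Define a one-way sweep
#'
#' @param path Dotted key path into the configuration
#'   (e.g. `"economics.discount_rate"`,
#'   `"epidemiology.cvd_incidence.point"`). The prefix `"scenario."`
#'   addresses the scenario under analysis, e.g.
#'   `"scenario.ten_year_salt_reduction_pct.point"`.
#' @param low,high Sweep bounds (`low <= high`).
#' @param label Human-readable parameter label.
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(path, low, high, label = path) {
  stopifnot(is.character(path), length(path) == 1, low <= high)
  structure(list(path = path, low = low, high = high, label = label),
            class = "sweep_spec")
}

apply_sweep_value <- function(cfg, scenario_name, path, value) {
  if (startsWith(path, "scenario.")) {
    path <- sub("^scenario\\.", paste0("scenarios.", scenario_name, "."), path)
  }
  cfg <- set_config_value(cfg, path, value)
  assert_valid_config(cfg)
  cfg
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs [cumulative_net_benefit()] with a single parameter set to its low
#' and then its high bound, all other parameters held at their point
#' estimates, and records the cumulative net benefit at the end of the
#' horizon for low, high, and point.
#'
#' @param cfg A validated `salt_config` (never modified).
#' @param scenario Scenario name.
#' @param spec A [sweep_spec()].
#' @return One-row data.frame: `label`, `low_value`, `high_value`, `nb_low`,
#'   `nb_high`, `nb_point`, `width` (absolute outcome range).
#' @export
one_way <- function(cfg, scenario, spec) {
  scen <- resolve_scenario(cfg, scenario)
  outcome <- function(c2) {
    s <- cumulative_net_benefit(c2, scen$name)
    s$cum_net_benefit[nrow(s)]
  }
  nb_point <- outcome(cfg)
  nb_low <- outcome(apply_sweep_value(cfg, scen$name, spec$path, spec$low))
  nb_high <- outcome(apply_sweep_value(cfg, scen$name, spec$path, spec$high))
  data.frame(
    label = spec$label,
    low_value = spec$low,
    high_value = spec$high,
    nb_low = nb_low,
    nb_high = nb_high,
    nb_point = nb_point,
    width = abs(nb_high - nb_low),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Tornado table of one-way sensitivity analyses
#'
#' @inheritParams one_way
#' @param specs List of [sweep_spec()] objects (at least one).
#' @return data.frame of [one_way()] rows sorted by descending `width`.
#' @export
tornado <- function(cfg, scenario, specs) {
  if (length(specs) < 1) stop("no sweep specs", call. = FALSE)
  rows <- lapply(specs, function(sp) one_way(cfg, scenario, sp))
  out <- do.call(rbind, rows)
  out[order(-out$width), , drop = FALSE]
}

#' Default sweep set for a scenario
#'
#' The discount rate over 0--4%, the scenario's decade salt-reduction effect
#' over its published range, the CVD incidence, prevalence, and mortality
#' rates over their 95% confidence intervals, and both relative risks over
#' theirs.
#'
#' @param cfg A `salt_config`.
#' @param scenario Scenario name.
#' @return List of [sweep_spec()] objects.
#' @export
default_sweep_specs <- function(cfg, scenario) {
  scen <- resolve_scenario(cfg, scenario)
  epi <- cfg$epidemiology
  rr <- cfg$relative_risks
  list(
    sweep_spec("scenario.ten_year_salt_reduction_pct.point",
               scen$ten_year_salt_reduction_pct$low,
               scen$ten_year_salt_reduction_pct$high,
               "Policy effect on salt intake"),
    sweep_spec("economics.discount_rate", 0, 0.04, "Discount rate"),
    sweep_spec("epidemiology.cvd_incidence.point",
               epi$cvd_incidence$low, epi$cvd_incidence$high,
               "CVD incidence"),
    sweep_spec("epidemiology.cvd_prevalence.point",
               epi$cvd_prevalence$low, epi$cvd_prevalence$high,
               "CVD prevalence"),
    sweep_spec("epidemiology.cvd_mortality.point",
               epi$cvd_mortality$low, epi$cvd_mortality$high,
               "CVD mortality"),
    sweep_spec("relative_risks.incidence_pct_per_g_sodium.point",
               rr$incidence_pct_per_g_sodium$low,
               rr$incidence_pct_per_g_sodium$high,
               "RR for CVD incidence"),
    sweep_spec("relative_risks.mortality_pct_per_10mmol_sodium.point",
               rr$mortality_pct_per_10mmol_sodium$low,
               rr$mortality_pct_per_10mmol_sodium$high,
               "RR for CVD mortality")
  )
}
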