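#' Constant annual intervention cost of a scenario
#'
#' The one-off England-scale policy and monitoring costs are scaled to the
#' modelled population (factor 2 by default, the modelled country being about
#' twice the size of England and Wales), annualized by dividing by the
#' horizon, and converted from GBP to USD.
#'
#' @param scenario A policy scenario list.
#' @param econ Economic parameter list (for the GBP/USD rate).
#' @param horizon Horizon in years.
#' @return Annual intervention cost in USD (constant across years).
#' @export
annual_intervention_cost <- function(scenario, econ, horizon) {
  stopifnot(horizon >= 1)
  scenario$population_scaling *
    (scenario$policy_cost_gbp + scenario$monitoring_cost_gbp) /
    horizon / econ$gbp_per_usd
}

#' Per-person annual healthcare costs by health state
#'
#' National inpatient expenditure is assigned to the acute state and
#' outpatient expenditure to the chronic state; dividing by the baseline
#' occupancy of each state gives fixed per-person-year unit costs.
#'
#' @param econ Economic parameter list.
#' @param baseline_state Baseline occupancy vector from [initial_state()].
#' @return List with `acute_usd_per_person_year` and
#'   `chronic_usd_per_person_year`.
#' @export
unit_state_costs <- function(econ, baseline_state) {
  if (baseline_state[["acute"]] <= 0 || baseline_state[["chronic"]] <= 0) {
    stop("baseline acute and chronic occupancies must be positive",
         call. = FALSE)
  }
  list(
    acute_usd_per_person_year =
      econ$inpatient_expenditure_usd / baseline_state[["acute"]],
    chronic_usd_per_person_year =
      econ$outpatient_expenditure_usd / baseline_state[["chronic"]]
  )
}

#' Averted-expenditure benefit stream of a scenario
#'
#' The benefit in year t is the healthcare expenditure averted relative to
#' the no-intervention trajectory: the occupancy reduction in the acute state
#' times the acute unit cost plus the occupancy reduction in the chronic
#' state times the chronic unit cost. Components are reported separately for
#' attribution by health state.
#'
#' @param null_traj Trajectory under no intervention ([run_cohort()] with
#'   `scenario = NULL`).
#' @param scen_traj Trajectory under the policy scenario.
#' @param units Unit costs from [unit_state_costs()].
#' @return data.frame with columns `year` (1..horizon), `benefit`,
#'   `benefit_acute`, `benefit_chronic` (USD).
#' @export
benefit_stream <- function(null_traj, scen_traj, units) {
  if (nrow(null_traj$occupancy) != nrow(scen_traj$occupancy)) {
    stop("trajectories have different horizons", call. = FALSE)
  }
  h <- nrow(null_traj$occupancy) - 1
  yrs <- seq_len(h)
  b_acute <- units$acute_usd_per_person_year *
    (null_traj$occupancy[yrs + 1, "acute"] -
       scen_traj$occupancy[yrs + 1, "acute"])
  b_chronic <- units$chronic_usd_per_person_year *
    (null_traj$occupancy[yrs + 1, "chronic"] -
       scen_traj$occupancy[yrs + 1, "chronic"])
  data.frame(
    year = yrs,
    benefit = as.numeric(b_acute + b_chronic),
    benefit_acute = as.numeric(b_acute),
    benefit_chronic = as.numeric(b_chronic),
    row.names = NULL
  )
}

#' Discount a yearly monetary stream
#'
#' @param stream Numeric vector of yearly values for years 1..horizon.
#' @param rate Annual discount rate (fraction, >= 0).
#' @param convention `"end"` (default): year-t value is divided by
#'   `(1 + rate)^t`; `"begin"`: by `(1 + rate)^(t - 1)`.
#' @return The discounted stream.
#' @export
discount_stream <- function(stream, rate, convention = c("end", "begin")) {
  stopifnot(rate >= 0)
  convention <- match.arg(convention)
  t <- seq_along(stream)
  expo <- if (convention == "end") t else t - 1
  stream / (1 + rate)^expo
}

#' Cumulative discounted net benefit of a scenario
#'
#' Runs the null and scenario trajectories, builds the constant intervention
#' cost stream and the averted-expenditure benefit stream, discounts both,
#' and accumulates. Net benefit is benefit minus cost.
#'
#' @param cfg A validated `salt_config`.
#' @param scenario A scenario name or scenario list.
#' @return A data.frame of class `net_benefit_series` with one row per year
#'   1..horizon and columns `year`, `cost`, `benefit`, `benefit_acute`,
#'   `benefit_chronic`, `disc_cost`, `disc_benefit`, `disc_net`, `cum_cost`,
#'   `cum_benefit`, `cum_net_benefit`, `scenario`; all monetary values in
#'   USD, cumulative columns are running sums of discounted values.
#' @export
cumulative_net_benefit <- function(cfg, scenario) {
  scen <- resolve_scenario(cfg, scenario)
  if (is.null(scen)) stop("a policy scenario is required", call. = FALSE)
  null_traj <- run_cohort(cfg, NULL)
  scen_traj <- run_cohort(cfg, scen)
  units <- unit_state_costs(cfg$economics, null_traj$occupancy[1, ])
  ben <- benefit_stream(null_traj, scen_traj, units)

  horizon <- as.integer(cfg$horizon_years)
  cost <- rep(annual_intervention_cost(scen, cfg$economics, horizon), horizon)
  rate <- cfg$economics$discount_rate
  conv <- cfg$discount_convention
  disc_cost <- discount_stream(cost, rate, conv)
  disc_benefit <- discount_stream(ben$benefit, rate, conv)

  out <- data.frame(
    year = ben$year,
    cost = cost,
    benefit = ben$benefit,
    benefit_acute = ben$benefit_acute,
    benefit_chronic = ben$benefit_chronic,
    disc_cost = disc_cost,
    disc_benefit = disc_benefit,
    disc_net = disc_benefit - disc_cost,
    cum_cost = cumsum(disc_cost),
    cum_benefit = cumsum(disc_benefit),
    cum_net_benefit = cumsum(disc_benefit - disc_cost),
    scenario = scen$name,
    row.names = NULL
  )
  class(out) <- c("net_benefit_series", "data.frame")
  attr(out, "discount_rate") <- rate
  out
}

#' Cumulative totals of a net-benefit series
#'
#' @param series A `net_benefit_series` from [cumulative_net_benefit()].
#' @return Named list: `scenario`, cumulative discounted `cost`, `benefit`,
#'   `net_benefit`, and the acute/chronic shares of the (undiscounted)
#'   benefit.
#' @export
net_benefit_totals <- function(series) {
  n <- nrow(series)
  total_ben <- sum(series$benefit)
  list(
    scenario = series$scenario[1],
    cost = series$cum_cost[n],
    benefit = series$cum_benefit[n],
    net_benefit = series$cum_net_benefit[n],
    share_acute = if (total_ben > 0) sum(series$benefit_acute) / total_ben else NA_real_,
    share_chronic = if (total_ben > 0) sum(series$benefit_chronic) / total_ben else NA_real_
  )
}
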