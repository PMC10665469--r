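# molar masses: sodium 22.99 g/mol, NaCl 58.44 g/mol
SODIUM_PER_SALT <- 22.99 / 58.44
MG_SODIUM_PER_MMOL <- 22.99

#' Annual salt-reduction rate implied by a decade target
#'
#' Policies are specified by the percentage of baseline salt intake removed
#' by the end of the horizon; intake is assumed to fall at a constant rate,
#' so the annual rate is the decade effect divided by its duration (in
#' percentage points of baseline per year). A 2% decade effect over 10 years
#' gives 0.2%/yr, 15% gives 1.5%/yr, and 20% gives 2.0%/yr.
#'
#' @param ten_year_pct Percent of baseline salt intake removed by the end of
#'   `duration_years` (0 <= value < 100).
#' @param duration_years Length of the phase-in period in years (>= 1).
#' @return Percentage points of baseline intake removed per year.
#' @export
annual_reduction_rate <- function(ten_year_pct, duration_years) {
  stopifnot(duration_years >= 1, ten_year_pct >= 0, ten_year_pct < 100)
  ten_year_pct / duration_years
}

#' Cumulative salt reduction achieved by a given year
#'
#' @param baseline_salt Baseline mean salt (NaCl) intake, g/day.
#' @param rate_pct_per_year Annual reduction rate, percentage points of
#'   baseline per year (see [annual_reduction_rate()]).
#' @param year Year index (0 = baseline, no reduction yet).
#' @return Cumulative reduction in g NaCl/day, capped at the baseline intake
#'   (intake never falls below zero).
#' @export
cumulative_salt_reduction <- function(baseline_salt, rate_pct_per_year, year) {
  stopifnot(year >= 0)
  min(baseline_salt, baseline_salt * rate_pct_per_year / 100 * year)
}

#' Convert salt (NaCl) mass to sodium mass
#'
#' @param salt_g Salt intake or reduction, g NaCl/day.
#' @return Sodium, g Na/day (`salt_g * 22.99 / 58.44`).
#' @export
salt_to_sodium <- function(salt_g) {
  if (any(salt_g < 0)) stop("salt mass must be non-negative", call. = FALSE)
  salt_g * SODIUM_PER_SALT
}

#' Convert sodium mass to millimoles
#'
#' @param sodium_g Sodium, g Na/day.
#' @return Sodium, mmol/day (`sodium_g * 1000 / 22.99`).
#' @export
sodium_to_mmol <- function(sodium_g) {
  if (any(sodium_g < 0)) stop("sodium mass must be non-negative", call. = FALSE)
  sodium_g * 1000 / MG_SODIUM_PER_MMOL
}

rr_multiplier <- function(effect_fraction, form, floor) {
  m <- switch(form,
    linear = 1 - effect_fraction,
    loglinear = exp(-effect_fraction),
    stop("unknown rr_form: ", form, call. = FALSE)
  )
  if (m <= 0) {
    stop("relative-risk multiplier is non-positive; the linear percent ",
         "scaling does not support an effect this large", call. = FALSE)
  }
  max(m, floor)
}

#' Incidence multiplier from a cumulative sodium reduction
#'
#' CVD incidence scales with daily sodium intake at
#' `incidence_pct_per_g_sodium` percent per gram. For a cumulative reduction
#' of `delta_sodium_g` the incidence multiplier is
#' `1 - pct/100 * delta_sodium_g` (the default linear form) or
#' `exp(-pct/100 * delta_sodium_g)` (log-linear), floored at
#' `floor` to stay positive.
#'
#' @param delta_sodium_g Cumulative reduction in sodium intake, g Na/day (>= 0).
#' @param rr Relative-risk parameter list (the `relative_risks` element of a
#'   `salt_config`).
#' @param form `"linear"` (default) or `"loglinear"`.
#' @param floor Minimum admissible multiplier (> 0).
#' @return Dimensionless multiplier in (0, 1].
#' @export
incidence_multiplier <- function(delta_sodium_g, rr, form = "linear",
                                 floor = 1e-6) {
  stopifnot(delta_sodium_g >= 0)
  pct <- if (is.list(rr$incidence_pct_per_g_sodium)) {
    rr$incidence_pct_per_g_sodium$point
  } else {
    rr$incidence_pct_per_g_sodium
  }
  rr_multiplier(pct / 100 * delta_sodium_g, form, floor)
}

#' Mortality multiplier from a cumulative sodium reduction
#'
#' CVD mortality scales with daily sodium intake at
#' `mortality_pct_per_10mmol_sodium` percent per 10 mmol of sodium. The
#' multiplier is `1 - pct/100 * mmol(delta)/10` under the default linear
#' form.
#'
#' @inheritParams incidence_multiplier
#' @return Dimensionless multiplier in (0, 1].
#' @export
mortality_multiplier <- function(delta_sodium_g, rr, form = "linear",
                                 floor = 1e-6) {
  stopifnot(delta_sodium_g >= 0)
  pct <- if (is.list(rr$mortality_pct_per_10mmol_sodium)) {
    rr$mortality_pct_per_10mmol_sodium$point
  } else {
    rr$mortality_pct_per_10mmol_sodium
  }
  rr_multiplier(pct / 100 * sodium_to_mmol(delta_sodium_g) / 10, form, floor)
}

#' Annual effect trajectory of a policy scenario
#'
#' Composes the annual salt decline, the salt-to-sodium conversion, and the
#' relative-risk scaling into a per-year table of cumulative reductions and
#' incidence/mortality multipliers. Each year's reduction takes full effect
#' within that year (no phase-in lag), and year 0 is the pre-intervention
#' baseline (zero reduction, multipliers 1).
#'
#' @param scenario A policy scenario list (an element of
#'   `baseline_config()$scenarios`).
#' @param epi Epidemiology parameter list (for the baseline salt intake).
#' @param rr Relative-risk parameter list.
#' @param horizon Horizon in years.
#' @param form Relative-risk composition form, `"linear"` or `"loglinear"`.
#' @param floor Minimum admissible multiplier.
#' @return A data.frame with one row per year 0..`horizon` and columns
#'   `year`, `salt_reduction_g`, `sodium_reduction_g`,
#'   `sodium_reduction_mmol`, `incidence_multiplier`, `mortality_multiplier`.
#' @export
effect_trajectory <- function(scenario, epi, rr, horizon,
                              form = "linear", floor = 1e-6) {
  rate <- annual_reduction_rate(scenario$ten_year_salt_reduction_pct$point,
                                horizon)
  years <- 0:horizon
  salt_red <- vapply(years, function(t) {
    cumulative_salt_reduction(epi$mean_salt_intake, rate, t)
  }, numeric(1))
  na_red <- salt_to_sodium(salt_red)
  data.frame(
    year = years,
    salt_reduction_g = salt_red,
    sodium_reduction_g = na_red,
    sodium_reduction_mmol = sodium_to_mmol(na_red),
    incidence_multiplier = vapply(na_red, incidence_multiplier, numeric(1),
                                  rr = rr, form = form, floor = floor),
    mortality_multiplier = vapply(na_red, mortality_multiplier, numeric(1),
                                  rr = rr, form = form, floor = floor)
  )
}
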