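STATE_NAMES <- c("healthy", "acute", "chronic", "dead")

#' Initial state occupancy of the closed cohort
#'
#' Splits the national cohort at baseline among the three living states using
#' the CVD incidence and prevalence rates: the acute pool holds one year of
#' incident cases, the chronic pool the remaining prevalent cases, and the
#' healthy pool the rest of the population. Occupancies are continuous person
#' units (cohort macro-simulation semantics, no integer rounding).
#'
#' @param epi Epidemiology parameter list (the `epidemiology` element of a
#'   `salt_config`).
#' @return Named numeric vector `(healthy, acute, chronic, dead)` with a
#'   `cycle` attribute set to 0.
#' @export
initial_state <- function(epi) {
  inc <- epi$cvd_incidence$point / 1e5
  prev <- epi$cvd_prevalence$point / 1e5
  if (prev < inc) {
    stop("epidemiology.cvd_prevalence: must be >= cvd_incidence", call. = FALSE)
  }
  pop <- epi$total_population
  acute <- inc * pop
  chronic <- (prev - inc) * pop
  state <- c(healthy = pop - acute - chronic, acute = acute,
             chronic = chronic, dead = 0)
  attr(state, "cycle") <- 0L
  state
}

#' Annual probability of death from non-CVD causes
#'
#' All-cause deaths minus CVD-attributed deaths, divided by the population.
#' The same probability applies to the healthy and chronic states (non-CVD
#' mortality is assumed equal regardless of CVD history).
#'
#' @inheritParams initial_state
#' @return Annual probability of dying from causes other than CVD.
#' @export
non_cvd_death_probability <- function(epi) {
  cvd_deaths <- epi$cvd_mortality$point / 1e5 * epi$total_population
  num <- epi$total_deaths - cvd_deaths
  if (num < 0) {
    stop("epidemiology.total_deaths: non-CVD death probability negative",
         call. = FALSE)
  }
  num / epi$total_population
}

#' Build the annual transition matrix
#'
#' Four states in row/column order (healthy, acute, chronic, dead). Healthy
#' people either suffer a first-ever acute CVD event, die from non-CVD
#' causes, or stay healthy; no one returns to the healthy state. The acute
#' state lasts exactly one cycle: patients survive to the chronic state or
#' die of the event (case fatality). Chronic patients either suffer a
#' recurrent acute event, die from non-CVD causes, or remain chronic. Death
#' is absorbing. Policy effects enter through the two multipliers: the
#' incidence multiplier scales both first-ever and recurrent events, the
#' mortality multiplier scales the acute case fatality.
#'
#' @inheritParams initial_state
#' @param incidence_multiplier Dimensionless scaling of CVD incidence, in (0, 1].
#' @param mortality_multiplier Dimensionless scaling of acute case fatality,
#'   in (0, 1].
#' @return 4x4 row-stochastic matrix with dimnames
#'   `(healthy, acute, chronic, dead)`.
#' @export
build_transition_matrix <- function(epi, incidence_multiplier = 1,
                                    mortality_multiplier = 1) {
  stopifnot(incidence_multiplier > 0, incidence_multiplier <= 1,
            mortality_multiplier > 0, mortality_multiplier <= 1)
  p_other <- non_cvd_death_probability(epi)
  p_ha <- epi$cvd_incidence$point / 1e5 * incidence_multiplier
  p_ad <- epi$acute_case_fatality * mortality_multiplier
  p_ca <- epi$chronic_recurrence * incidence_multiplier

  p_hh <- 1 - p_ha - p_other
  p_ac <- 1 - p_ad
  p_cc <- 1 - p_ca - p_other
  if (p_hh < 0) {
    stop("healthy row: transition probabilities exceed 1", call. = FALSE)
  }
  if (p_ac < 0) {
    stop("acute row: case fatality exceeds 1", call. = FALSE)
  }
  if (p_cc < 0) {
    stop("chronic row: transition probabilities exceed 1", call. = FALSE)
  }
  matrix(
    c(p_hh, p_ha, 0,    p_other,
      0,    0,    p_ac, p_ad,
      0,    p_ca, p_cc, p_other,
      0,    0,    0,    1),
    nrow = 4, byrow = TRUE,
    dimnames = list(STATE_NAMES, STATE_NAMES)
  )
}

#' Advance the cohort one annual cycle
#'
#' Left-multiplies the occupancy row vector by the transition matrix and
#' increments the cycle counter. Total occupancy is conserved because the
#' matrix is row-stochastic.
#'
#' @param state Named occupancy vector as returned by [initial_state()].
#' @param matrix 4x4 transition matrix from [build_transition_matrix()].
#' @return The occupancy vector after one cycle.
#' @export
step_cohort <- function(state, matrix) {
  if (length(state) != nrow(matrix) || ncol(matrix) != length(state)) {
    stop("state and transition matrix dimensions do not match", call. = FALSE)
  }
  nxt <- as.numeric(state %*% matrix)
  names(nxt) <- names(state)
  cyc <- attr(state, "cycle")
  attr(nxt, "cycle") <- if (is.null(cyc)) NULL else cyc + 1L
  nxt
}

resolve_scenario <- function(cfg, scenario) {
  if (is.null(scenario)) return(NULL)
  if (is.character(scenario)) {
    if (!scenario %in% names(cfg$scenarios)) {
      stop("unknown scenario '", scenario, "'; known scenarios: ",
           paste(names(cfg$scenarios), collapse = ", "), call. = FALSE)
    }
    return(cfg$scenarios[[scenario]])
  }
  scenario
}

#' Run the closed-cohort simulation
#'
#' Simulates the cohort over the configured horizon in annual cycles. Under
#' the null scenario (`scenario = NULL`) transition probabilities are
#' constant; under a policy scenario the matrix is rebuilt each year with the
#' incidence and mortality multipliers implied by that year's cumulative salt
#' reduction (see [effect_trajectory()]).
#'
#' @param cfg A validated `salt_config`.
#' @param scenario A scenario name, a scenario list, or `NULL` for the
#'   no-intervention baseline.
#' @return A `salt_trajectory`: list with `occupancy` (a `(horizon+1) x 4`
#'   matrix of person counts, rows = cycles 0..horizon), `scenario` (name),
#'   `matrices` (per-cycle transition matrices), and `effects` (the effect
#'   trajectory, or `NULL` for the null scenario).
#' @export
run_cohort <- function(cfg, scenario = NULL) {
  scen <- resolve_scenario(cfg, scenario)
  epi <- cfg$epidemiology
  horizon <- as.integer(cfg$horizon_years)
  eff <- if (is.null(scen)) NULL else {
    effect_trajectory(scen, epi, cfg$relative_risks, horizon,
                      form = cfg$rr_form, floor = cfg$multiplier_floor)
  }

  occ <- matrix(NA_real_, nrow = horizon + 1, ncol = 4,
                dimnames = list(0:horizon, STATE_NAMES))
  occ[1, ] <- initial_state(epi)
  matrices <- vector("list", horizon)
  state <- occ[1, ]
  for (t in seq_len(horizon)) {
    im <- if (is.null(eff)) 1 else eff$incidence_multiplier[t + 1]
    mm <- if (is.null(eff)) 1 else eff$mortality_multiplier[t + 1]
    P <- build_transition_matrix(epi, im, mm)
    state <- as.numeric(state %*% P)
    occ[t + 1, ] <- state
    matrices[[t]] <- P
  }
  structure(
    list(
      occupancy = occ,
      scenario = if (is.null(scen)) "null" else scen$name,
      matrices = matrices,
      effects = eff
    ),
    class = "salt_trajectory"
  )
}

#' @export
as.data.frame.salt_trajectory <- function(x, ...) {
  data.frame(
    cycle = as.integer(rownames(x$occupancy)),
    healthy = x$occupancy[, "healthy"],
    acute = x$occupancy[, "acute"],
    chronic = x$occupancy[, "chronic"],
    dead = x$occupancy[, "dead"],
    scenario = x$scenario,
    row.names = NULL
  )
}

#' @export
print.salt_trajectory <- function(x, ...) {
  h <- nrow(x$occupancy) - 1
  cat(sprintf("<salt_trajectory> scenario '%s', %d annual cycles\n",
              x$scenario, h))
  cat(sprintf("  final occupancy: healthy %.0f, acute %.0f, chronic %.0f, dead %.0f\n",
              x$occupancy[h + 1, 1], x$occupancy[h + 1, 2],
              x$occupancy[h + 1, 3], x$occupancy[h + 1, 4]))
  invisible(x)
}
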