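jitter_value <- function(x, scale) x * stats::runif(1, 1 - scale, 1 + scale)

# one multiplicative factor per point+CI block keeps low <= point <= high
jitter_block <- function(block, scale) {
  f <- stats::runif(1, 1 - scale, 1 + scale)
  lapply(block, function(v) v * f)
}

jitter_config <- function(base, scale) {
  cfg <- base
  epi <- cfg$epidemiology
  epi$total_population <- jitter_value(epi$total_population, scale)
  epi$total_deaths <- jitter_value(epi$total_deaths, scale)
  epi$mean_salt_intake <- jitter_value(epi$mean_salt_intake, scale)
  epi$cvd_incidence <- jitter_block(epi$cvd_incidence, scale)
  epi$cvd_prevalence <- jitter_block(epi$cvd_prevalence, scale)
  epi$cvd_mortality <- jitter_block(epi$cvd_mortality, scale)
  epi$acute_case_fatality <- min(1, jitter_value(epi$acute_case_fatality, scale))
  epi$chronic_recurrence <- min(1, jitter_value(epi$chronic_recurrence, scale))
  cfg$epidemiology <- epi

  rr <- cfg$relative_risks
  rr$incidence_pct_per_g_sodium <- jitter_block(rr$incidence_pct_per_g_sodium, scale)
  rr$mortality_pct_per_10mmol_sodium <- jitter_block(rr$mortality_pct_per_10mmol_sodium, scale)
  cfg$relative_risks <- rr

  eco <- cfg$economics
  eco$inpatient_expenditure_usd <- jitter_value(eco$inpatient_expenditure_usd, scale)
  eco$outpatient_expenditure_usd <- jitter_value(eco$outpatient_expenditure_usd, scale)
  eco$discount_rate <- min(1, jitter_value(eco$discount_rate, scale))
  eco$gbp_per_usd <- jitter_value(eco$gbp_per_usd, scale)
  eco$jpy_per_usd <- jitter_value(eco$jpy_per_usd, scale)
  cfg$economics <- eco

  for (nm in names(cfg$scenarios)) {
    sc <- cfg$scenarios[[nm]]
    sc$ten_year_salt_reduction_pct <-
      jitter_block(sc$ten_year_salt_reduction_pct, scale)
    sc$policy_cost_gbp <- jitter_value(sc$policy_cost_gbp, scale)
    sc$monitoring_cost_gbp <- jitter_value(sc$monitoring_cost_gbp, scale)
    sc$population_scaling <- jitter_value(sc$population_scaling, scale)
    cfg$scenarios[[nm]] <- sc
  }
  cfg
}

#' Generate perturbed parameter sets
#'
#' Applies seeded uniform multiplicative jitter (`U(1 - scale, 1 + scale)`)
#' to every numeric parameter of a base configuration. Point estimates and
#' their confidence bounds within one parameter are scaled by a common
#' factor, which preserves their ordering; each candidate is validated and
#' resampled until valid (bounded retries). The same seed always yields the
#' same list.
#'
#' @param base A valid `salt_config` to perturb.
#' @param n_sets Number of configurations to generate (>= 1).
#' @param relative_scale Jitter half-width as a fraction (e.g. 0.2); 0 yields
#'   exact copies.
#' @param seed Integer RNG seed; the caller's RNG state is left untouched.
#' @param max_retries Retry budget per configuration.
#' @return List of `n_sets` validated `salt_config` objects.
#' @export
perturbed_configs <- function(base, n_sets, relative_scale = 0.2, seed = 1L,
                              max_retries = 100L) {
  stopifnot(n_sets >= 1, relative_scale >= 0)
  withr::with_seed(seed, {
    lapply(seq_len(n_sets), function(i) {
      for (try in seq_len(max_retries)) {
        cand <- jitter_config(base, relative_scale)
        viol <- validate_config(cand)
        if (length(viol) == 0) return(cand)
      }
      stop("perturbation retry budget exhausted; binding constraint: ",
           viol[1], call. = FALSE)
    })
  })
}

#' Write perturbed parameter sets to YAML files
#'
#' @inheritParams perturbed_configs
#' @param out_dir Directory to write `config_001.yaml`, ... into (created if
#'   missing).
#' @return Character vector of written file paths, invisibly.
#' @export
write_fixture_configs <- function(base, n_sets, relative_scale = 0.2,
                                  seed = 1L, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfgs <- perturbed_configs(base, n_sets, relative_scale, seed)
  paths <- file.path(out_dir, sprintf("config_%03d.yaml", seq_len(n_sets)))
  for (i in seq_len(n_sets)) write_config(cfgs[[i]], paths[i])
  invisible(paths)
}

#' Independent brute-force cohort simulation (verification oracle)
#'
#' Computes the same trajectory as [run_cohort()] but with a deliberately
#' independent implementation: plain per-state scalar arithmetic inside an
#' explicit year loop, with the salt decline, unit conversions, and
#' relative-risk multipliers recomputed from first principles rather than
#' through the shared matrix and effect-trajectory code. Used in tests to
#' cross-check the engine.
#'
#' @inheritParams run_cohort
#' @return A `salt_trajectory` (without per-cycle matrices).
#' @export
oracle_run <- function(cfg, scenario = NULL) {
  scen <- resolve_scenario(cfg, scenario)
  epi <- cfg$epidemiology
  horizon <- as.integer(cfg$horizon_years)
  pop <- epi$total_population

  a <- epi$cvd_incidence$point / 1e5 * pop
  c_ <- (epi$cvd_prevalence$point - epi$cvd_incidence$point) / 1e5 * pop
  h <- pop - a - c_
  d <- 0
  p_other <- (epi$total_deaths - epi$cvd_mortality$point / 1e5 * pop) / pop

  occ <- matrix(NA_real_, nrow = horizon + 1, ncol = 4,
                dimnames = list(0:horizon, c("healthy", "acute", "chronic", "dead")))
  occ[1, ] <- c(h, a, c_, d)

  for (t in seq_len(horizon)) {
    if (is.null(scen)) {
      im <- 1
      mm <- 1
    } else {
      pct_per_year <- scen$ten_year_salt_reduction_pct$point / horizon
      salt_red <- min(epi$mean_salt_intake,
                      epi$mean_salt_intake * pct_per_year / 100 * t)
      na_red <- salt_red * 22.99 / 58.44
      e_inc <- cfg$relative_risks$incidence_pct_per_g_sodium$point / 100 * na_red
      e_mor <- cfg$relative_risks$mortality_pct_per_10mmol_sodium$point / 100 *
        (na_red * 1000 / 22.99) / 10
      if (cfg$rr_form == "loglinear") {
        im <- exp(-e_inc)
        mm <- exp(-e_mor)
      } else {
        im <- 1 - e_inc
        mm <- 1 - e_mor
      }
      if (im <= 0 || mm <= 0) {
        stop("relative-risk multiplier is non-positive", call. = FALSE)
      }
      im <- max(im, cfg$multiplier_floor)
      mm <- max(mm, cfg$multiplier_floor)
    }

    p_ha <- epi$cvd_incidence$point / 1e5 * im
    p_ad <- epi$acute_case_fatality * mm
    p_ca <- epi$chronic_recurrence * im
    if (1 - p_ha - p_other < 0 || 1 - p_ad < 0 || 1 - p_ca - p_other < 0) {
      stop("transition probabilities exceed 1", call. = FALSE)
    }

    h2 <- h * (1 - p_ha - p_other)
    a2 <- h * p_ha + c_ * p_ca
    c2 <- a * (1 - p_ad) + c_ * (1 - p_ca - p_other)
    d2 <- d + h * p_other + a * p_ad + c_ * p_other
    h <- h2; a <- a2; c_ <- c2; d <- d2
    occ[t + 1, ] <- c(h, a, c_, d)
  }

  structure(
    list(occupancy = occ,
         scenario = if (is.null(scen)) "null" else scen$name,
         matrices = NULL, effects = NULL),
    class = "salt_trajectory"
  )
}
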