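test_that("initial state splits the cohort by incidence and prevalence", {
  epi <- baseline_config()$epidemiology
  s0 <- initial_state(epi)
  pop <- 126197000
  expect_equal(s0[["acute"]], 1203 / 1e5 * pop)           # one year of incident cases
  expect_equal(s0[["chronic"]], (13500 - 1203) / 1e5 * pop)
  expect_equal(s0[["healthy"]], pop * (1 - 13500 / 1e5))
  expect_identical(s0[["dead"]], 0)
  expect_equal(sum(s0), pop)
  expect_identical(attr(s0, "cycle"), 0L)

  epi0 <- epi
  epi0$cvd_incidence$point <- 0
  epi0$cvd_prevalence$point <- 0
  s <- initial_state(epi0)
  expect_equal(s[["healthy"]], pop)
  expect_equal(s[["acute"]] + s[["chronic"]] + s[["dead"]], 0)

  epi_bad <- epi
  epi_bad$cvd_prevalence$point <- 1000
  expect_error(initial_state(epi_bad), "cvd_prevalence")
})

test_that("non-CVD death probability subtracts CVD-attributed deaths", {
  epi <- baseline_config()$epidemiology
  expect_equal(non_cvd_death_probability(epi),
               (1381093 - 291 / 1e5 * 126197000) / 126197000)
  expect_equal(round(non_cvd_death_probability(epi), 6), 0.008034)

  epi2 <- epi
  epi2$cvd_mortality$point <- 0
  expect_equal(non_cvd_death_probability(epi2), 1381093 / 126197000)

  epi3 <- epi
  epi3$total_deaths <- 291 / 1e5 * 126197000
  expect_equal(non_cvd_death_probability(epi3), 0)

  epi4 <- epi
  epi4$total_deaths <- 100
  expect_error(non_cvd_death_probability(epi4), "negative")
})

test_that("transition matrix has the four-state structure", {
  epi <- baseline_config()$epidemiology
  P <- build_transition_matrix(epi, 1, 1)
  expect_row_stochastic(P)
  expect_equal(unname(P["dead", ]), c(0, 0, 0, 1))       # absorbing
  expect_identical(P["healthy", "chronic"], 0)           # no direct jump
  expect_identical(P["acute", "healthy"], 0)             # no recovery to healthy
  expect_identical(P["acute", "acute"], 0)               # acute lasts one cycle
  expect_identical(P["chronic", "healthy"], 0)
  expect_equal(P["healthy", "acute"], 0.01203)
  expect_equal(P["acute", "chronic"], 1 - epi$acute_case_fatality)
  expect_equal(P["chronic", "acute"], epi$chronic_recurrence)
  expect_equal(P["healthy", "dead"], non_cvd_death_probability(epi))
  expect_equal(P["chronic", "dead"], non_cvd_death_probability(epi))
})

test_that("multipliers scale incidence and case fatality as specified", {
  epi <- baseline_config()$epidemiology
  P <- build_transition_matrix(epi, 0.5, 0.98)
  expect_equal(P["healthy", "acute"], 0.01203 * 0.5)
  expect_equal(P["chronic", "acute"], epi$chronic_recurrence * 0.5)
  expect_equal(P["acute", "dead"], epi$acute_case_fatality * 0.98)
  expect_row_stochastic(P)

  expect_error(build_transition_matrix(epi, 0, 1))        # multipliers in (0, 1]
  expect_error(build_transition_matrix(epi, 1, 1.5))

  epi_bad <- epi
  epi_bad$chronic_recurrence <- 0.999
  expect_error(build_transition_matrix(epi_bad, 1, 1), "chronic row")
})

test_that("one cycle is a vector-matrix product that conserves the cohort", {
  epi <- baseline_config()$epidemiology
  s0 <- initial_state(epi)

  id <- diag(4)
  s1 <- step_cohort(s0, id)
  expect_equal(as.numeric(s1), as.numeric(s0))
  expect_identical(attr(s1, "cycle"), 1L)

  P <- build_transition_matrix(epi, 1, 1)
  all_dead <- c(healthy = 0, acute = 0, chronic = 0, dead = 1e6)
  expect_equal(unname(step_cohort(all_dead, P)), c(0, 0, 0, 1e6))

  s1 <- step_cohort(s0, P)
  # new acute pool: first-ever events from healthy plus recurrences from chronic
  expect_equal(s1[["acute"]],
               s0[["healthy"]] * 0.01203 + s0[["chronic"]] * epi$chronic_recurrence)
  expect_equal(sum(s1), sum(s0))

  expect_error(step_cohort(c(1, 2, 3), P), "dimensions")
})

test_that("cohort runs conserve people, deplete healthy, and accumulate dead", {
  cfg <- baseline_config()
  pop <- cfg$epidemiology$total_population
  for (scen in c(list(NULL), as.list(names(cfg$scenarios)))) {
    traj <- run_cohort(cfg, scen)
    expect_equal(nrow(traj$occupancy), cfg$horizon_years + 1)
    expect_true(all(traj$occupancy >= 0))
    expect_equal(rowSums(traj$occupancy), setNames(rep(pop, 11), 0:10),
                 tolerance = 1e-6)
    expect_true(all(diff(traj$occupancy[, "dead"]) >= 0))
    expect_true(all(diff(traj$occupancy[, "healthy"]) <= 0))
  }
})

test_that("null run equals repeated matrix powers and zero effect equals null", {
  cfg <- baseline_config()
  null_traj <- run_cohort(cfg, NULL)
  # time-constant rates: one matrix reused every cycle
  for (P in null_traj$matrices) expect_identical(P, null_traj$matrices[[1]])
  P <- null_traj$matrices[[1]]
  s <- null_traj$occupancy[1, ]
  Pt <- diag(4)
  for (t in 1:10) {
    Pt <- Pt %*% P
    expect_equal(unname(null_traj$occupancy[t + 1, ]),
                 as.numeric(s %*% Pt), tolerance = 1e-12)
  }

  cfg0 <- with_zero_effect_scenario(cfg)
  zero_traj <- run_cohort(cfg0, "no_effect")
  expect_equal(zero_traj$occupancy, null_traj$occupancy, tolerance = 1e-15)
})

test_that("policy scenarios lower the first-event probability year on year", {
  cfg <- baseline_config()
  traj <- run_cohort(cfg, "mandatory_best")
  p_ha <- vapply(traj$matrices, function(P) P["healthy", "acute"], numeric(1))
  expect_true(all(diff(p_ha) < 0))
  expect_error(run_cohort(cfg, "soda_tax"), "unknown scenario")

  df <- as.data.frame(traj)
  expect_identical(names(df),
                   c("cycle", "healthy", "acute", "chronic", "dead", "scenario"))
  expect_identical(df$scenario[1], "mandatory_best")
})
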