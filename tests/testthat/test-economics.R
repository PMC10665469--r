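test_that("intervention costs are scaled, annualized, and converted to USD", {
  cfg <- baseline_config()
  eco <- cfg$economics
  # labeling: 20 M GBP policy + 20 M GBP monitoring, doubled, over 10 years
  expect_equal(annual_intervention_cost(cfg$scenarios$labeling, eco, 10),
               2 * (20e6 + 20e6) / 10 / 0.783)
  # scenario with no monitoring: policy cost alone
  sc <- cfg$scenarios$labeling
  sc$monitoring_cost_gbp <- 0
  expect_equal(annual_intervention_cost(sc, eco, 10), 2 * 20e6 / 10 / 0.783)
  expect_equal(round(annual_intervention_cost(sc, eco, 10)), 5108557)
  sc$policy_cost_gbp <- 0
  expect_identical(annual_intervention_cost(sc, eco, 10), 0)
  # best-case mandatory and voluntary carry identical costs by construction
  expect_equal(
    annual_intervention_cost(cfg$scenarios$mandatory_best, eco, 10),
    annual_intervention_cost(cfg$scenarios$voluntary, eco, 10))
})

test_that("unit state costs divide national expenditure by baseline occupancy", {
  cfg <- baseline_config()
  s0 <- initial_state(cfg$epidemiology)
  u <- unit_state_costs(cfg$economics, s0)
  expect_equal(u$acute_usd_per_person_year, 34549123934 / s0[["acute"]])
  expect_equal(round(u$acute_usd_per_person_year), 22757)
  expect_equal(u$chronic_usd_per_person_year, 21747546097 / s0[["chronic"]])
  expect_equal(round(u$chronic_usd_per_person_year, 1), 1401.4)

  eco2 <- cfg$economics
  eco2$inpatient_expenditure_usd <- 2 * eco2$inpatient_expenditure_usd
  eco2$outpatient_expenditure_usd <- 2 * eco2$outpatient_expenditure_usd
  u2 <- unit_state_costs(eco2, s0)
  expect_equal(u2$acute_usd_per_person_year, 2 * u$acute_usd_per_person_year)
  expect_equal(u2$chronic_usd_per_person_year, 2 * u$chronic_usd_per_person_year)

  expect_error(unit_state_costs(cfg$economics,
                                c(healthy = 1, acute = 0, chronic = 1, dead = 0)),
               "positive")
})

test_that("benefit stream prices occupancy differences by state", {
  cfg <- baseline_config()
  null_traj <- run_cohort(cfg, NULL)
  units <- unit_state_costs(cfg$economics, null_traj$occupancy[1, ])

  # identical trajectories: no averted expenditure
  b0 <- benefit_stream(null_traj, null_traj, units)
  expect_true(all(b0$benefit == 0))

  # toy single-year case: 10 fewer acute patients at 10 USD each
  toy_null <- structure(list(occupancy = matrix(
    c(1000, 1000, 100, 100, 10, 10, 0, 0), nrow = 2,
    dimnames = list(0:1, c("healthy", "acute", "chronic", "dead")))),
    class = "salt_trajectory")
  toy_scen <- toy_null
  toy_scen$occupancy[2, "acute"] <- 90
  toy_units <- list(acute_usd_per_person_year = 10,
                    chronic_usd_per_person_year = 7)
  b <- benefit_stream(toy_null, toy_scen, toy_units)
  expect_equal(b$benefit, 100)
  expect_equal(b$benefit_acute, 100)
  expect_equal(b$benefit_chronic, 0)

  # widening trajectory gap: yearly benefits never shrink
  scen_traj <- run_cohort(cfg, "mandatory_best")
  b <- benefit_stream(null_traj, scen_traj, units)
  expect_true(all(diff(b$benefit) >= 0))

  short <- structure(list(occupancy = null_traj$occupancy[1:5, ]),
                     class = "salt_trajectory")
  expect_error(benefit_stream(null_traj, short, units), "horizon")
})

test_that("discounting follows the end-of-cycle convention", {
  expect_identical(discount_stream(c(5, 7, 9), 0), c(5, 7, 9))
  # unit stream over 10 years at 2%: closed-form annuity factor
  expect_equal(sum(discount_stream(rep(1, 10), 0.02)),
               (1 - 1.02^-10) / 0.02)
  expect_equal(round(sum(discount_stream(rep(1, 10), 0.02)), 4), 8.9826)
  expect_equal(discount_stream(c(102), 0.02), 100)
  # begin-of-cycle shifts the exponent by one year
  expect_equal(discount_stream(c(1, 1), 0.02, "begin"), c(1, 1 / 1.02))
  expect_error(discount_stream(1, -0.1))
})

test_that("zero-effect scenarios isolate the cost side of the ledger", {
  cfg <- with_zero_effect_scenario(baseline_config())
  nb <- cumulative_net_benefit(cfg, "no_effect")
  expect_true(all(nb$benefit == 0))
  expect_true(all(nb$cost == 0))
  expect_true(all(nb$cum_net_benefit == 0))

  cfg2 <- with_zero_effect_scenario(baseline_config(),
                                    policy_cost_gbp = 1e6,
                                    monitoring_cost_gbp = 5e5)
  nb2 <- cumulative_net_benefit(cfg2, "no_effect")
  expect_true(all(nb2$benefit == 0))
  expect_equal(nb2$cum_net_benefit, -nb2$cum_cost)
})

test_that("net-benefit series is internally consistent", {
  cfg <- baseline_config()
  nb <- cumulative_net_benefit(cfg, "voluntary")
  expect_identical(nrow(nb), 10L)
  expect_equal(nb$disc_net, nb$disc_benefit - nb$disc_cost)
  expect_equal(nb$benefit, nb$benefit_acute + nb$benefit_chronic)
  expect_equal(nb$cum_net_benefit, cumsum(nb$disc_benefit) - cumsum(nb$disc_cost))
  expect_equal(nb$disc_cost, nb$cost / 1.02^(1:10))
  tot <- net_benefit_totals(nb)
  expect_equal(tot$net_benefit, tot$benefit - tot$cost)
  expect_equal(tot$share_acute + tot$share_chronic, 1)
})

test_that("benefits rank by effect size; shared effects share benefits", {
  cfg <- baseline_config()
  nb <- lapply(names(cfg$scenarios), function(nm) {
    net_benefit_totals(cumulative_net_benefit(cfg, nm))
  })
  names(nb) <- names(cfg$scenarios)
  ben <- vapply(nb, `[[`, numeric(1), "benefit")
  expect_gt(ben[["mandatory_best"]], ben[["voluntary"]])
  expect_gt(ben[["voluntary"]], ben[["media_campaign"]])
  expect_identical(ben[["media_campaign"]], ben[["labeling"]])
  # the two mandatory cost cases differ only in cost
  expect_identical(ben[["mandatory_best"]], ben[["mandatory_worst"]])
  expect_gt(nb$mandatory_worst$cost, nb$mandatory_best$cost)
})
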