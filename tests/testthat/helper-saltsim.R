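# shared helpers for the suite

# baseline config with a scenario that has no salt effect, optionally with cost
with_zero_effect_scenario <- function(cfg = baseline_config(),
                                      policy_cost_gbp = 0,
                                      monitoring_cost_gbp = 0) {
  cfg$scenarios$no_effect <- list(
    name = "no_effect",
    ten_year_salt_reduction_pct = list(point = 0, low = 0, high = 0),
    policy_cost_gbp = policy_cost_gbp,
    monitoring_cost_gbp = monitoring_cost_gbp,
    population_scaling = 2
  )
  cfg
}

expect_row_stochastic <- function(P) {
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-12)
}

max_rel_diff <- function(a, b) {
  max(abs(a - b) / pmax(abs(a), abs(b), 1))
}
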