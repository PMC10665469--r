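# saltsim

Deterministic Markov cohort simulation of population-wide dietary salt
reduction policies and their net economic benefit through averted
cardiovascular disease (CVD) healthcare expenditure.

`saltsim` is aimed at health-economic modellers and nutrition-policy
analysts. It implements a four-state annual-cycle cohort model of a closed
national population (healthy → acute CVD → chronic CVD → dead, with death
absorbing and no return to health), in which policy scenarios lower mean
dietary salt intake at a constant annual rate. The cumulative sodium
reduction Δ scales CVD incidence by `1 − 0.06·Δ` (6% per g Na/day) and acute
case fatality by `1 − 0.01·(mmol(Δ)/10)` (1% per 10 mmol Na/day). Benefits
are averted inpatient (acute state) and outpatient (chronic state)
expenditures priced at fixed per-person-year unit costs; costs are
England-scale policy plus monitoring costs, doubled to population scale,
annualized, and converted to USD; both are discounted at 2%/yr and
accumulated over a 10-year horizon. Deterministic one-way (tornado)
sensitivity analysis, a YAML parameter model with provenance tracking,
seeded synthetic parameter perturbation, and an independent brute-force
simulation oracle complete the package. The scientific background and every
modelling choice are documented in `vignettes/salt-policy-model.Rmd`.

Four model inputs are not published in the primary sources and ship as
flagged placeholders (case fatality 0.10/yr, recurrence 0.05/yr,
media-campaign cost 35 M GBP, monitoring 2 M GBP/yr); monetary totals
therefore carry those assumptions, and every pipeline run warns about them.

## Worked example

```r
library(saltsim)
cfg <- baseline_config()                      # packaged 2019 Japan defaults
initial_state(cfg$epidemiology)
#>   healthy     acute   chronic      dead
#> 109160405   1518150  15518445         0

nb <- cumulative_net_benefit(cfg, "mandatory_best")
round(unlist(net_benefit_totals(nb)[c("cost", "benefit", "net_benefit")]) / 1e6, 1)
#>        cost     benefit net_benefit
#>        45.9     11696.6     11650.7
```

Mandatory reformulation under the best-case cost assumption costs a
discounted 45.9 M USD over the decade, averts 11,696.6 M USD of CVD
healthcare expenditure, and nets 11,650.7 M USD. Ranked by cumulative net
benefit on the defaults: mandatory (best case) > voluntary > mandatory
(worst case) > labeling > media campaign, all positive by year 10, with the
media campaign and labeling sharing one benefit stream (identical 2% decade
effect) and differing only in cost.

The full analysis lives in three drivers, run from the repository root:

```sh
Rscript analysis/01_baseline_cohort.R     # initial split, null trajectory
Rscript analysis/02_policy_scenarios.R    # five policy/cost cases, ranking
Rscript analysis/03_sensitivity.R         # tornado tables per scenario
```

Outputs (trajectory, net-benefit, ranking, and tornado CSVs plus a JSON
summary and run manifest) are written under `results/`.

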