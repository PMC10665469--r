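---
title: "A Markov cohort model of salt-reduction policies and CVD healthcare costs"
author: "saltsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of salt-reduction policies and CVD healthcare costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`saltsim` simulates the economic consequences of population-wide dietary salt
reduction policies for cardiovascular disease (CVD) with a deterministic,
discrete-time Markov cohort macro-simulation. A closed national cohort (the
Japanese population of 2019, 126,197,000 people, with no births or migration)
moves among four mutually exclusive health states in annual cycles:

* **healthy** — no CVD history;
* **acute CVD** — hospitalized for a first-ever or recurrent CVD event; this
  state lasts exactly one cycle;
* **chronic CVD** — survivors of an acute event under continuing outpatient
  care; they can never return to the healthy state;
* **dead** — absorbing.

Writing $p_{ij}$ for the annual transition probabilities, the healthy row is
$(1 - p_{HA} - p_{HD},\; p_{HA},\; 0,\; p_{HD})$, the acute row
$(0, 0, 1 - p_{AD}, p_{AD})$, the chronic row
$(0,\; p_{CA},\; 1 - p_{CA} - p_{CD},\; p_{CD})$, and the dead row
$(0,0,0,1)$. Here $p_{HA}$ is the annual CVD incidence rate (1,203 per
100,000), $p_{AD}$ the acute case fatality, $p_{CA}$ the annual recurrence
probability among chronic patients, and $p_{HD} = p_{CD}$ the non-CVD death
probability — all-cause deaths minus CVD-attributed deaths over the
population, the same for people with and without CVD history (a deliberate
simplifying assumption). At baseline the cohort is split by the incidence and
prevalence rates: one year of incident cases forms the acute pool, the
remaining prevalent cases the chronic pool, everyone else is healthy.

Per-100,000 annual rates are used directly as annual probabilities rather
than being converted through exponential hazards: at the magnitudes involved
(at most 0.0135/yr) the two differ by less than a part in a hundred, far
below the other uncertainties in the model, and the source framework states
no hazard formulation.

## Policy scenarios and risk scaling

Four policies are modelled, each defined by the percentage of baseline mean
salt intake (10.1 g NaCl/day) it removes by the end of the 10-year horizon: a
national media campaign and front-of-pack traffic-light labeling (2%, range
1–5), voluntary reformulation of processed foods (15%, range 5–20), and
mandatory reformulation (20%, range 10–32); mandatory reformulation is run
under both a best-case and a worst-case policy-cost assumption, giving five
policy/cost cases. Intake declines linearly — the decade effect divided by
the horizon, i.e. 0.2, 1.5 and 2.0 percentage points of baseline per year —
and each year's reduction takes full effect on disease risk within that year,
with no phase-in lag.

The cumulative salt reduction is converted to sodium by the molar-mass ratio
$22.99/58.44$ and scaled by two published relative risks: CVD incidence
changes 6% (95% CI 1–11) per gram of daily sodium and CVD mortality 1% (95%
CI 0.2–1.7) per 10 mmol of daily sodium. For a cumulative sodium reduction
$\Delta$ the year's multipliers are

$$m_{\text{inc}} = 1 - \tfrac{6}{100}\,\Delta, \qquad
  m_{\text{mort}} = 1 - \tfrac{1}{100}\,\tfrac{\Delta \cdot 1000/22.99}{10},$$

applied to the incidence terms ($p_{HA}$ and the recurrence $p_{CA}$) and to
the acute case fatality $p_{AD}$ respectively. The "per 1 g"/"per 10 mmol"
units are read as *sodium*, not salt, because the risk estimates come from
sodium-intake meta-analyses. Percent effects compose linearly in $\Delta$
rather than log-linearly; at the reductions reachable here (< 1 g Na/day) the
two differ only in the third decimal, and `rr_form = "loglinear"`
switches to $\exp(-\text{pct}\,\Delta)$ for sensitivity. Multipliers are
floored at `multiplier_floor` (default $10^{-6}$) and an effect large enough
to drive a linear multiplier non-positive is a domain error.

## Costs, benefits, discounting

Intervention costs are England-scale policy plus monitoring costs in GBP,
doubled (the modelled population being roughly twice that of England and
Wales; the exact ratio ≈ 2.123 can be configured instead), annualized by
dividing by the horizon, and converted at the 2019 IMF annual average rates
(0.783 GBP/USD; yen figures use 109.01 JPY/USD). The labeling policy cost is
1,000 GBP per stock-keeping line × 20,000 product lines; the worst-case
mandatory cost is 25,000 GBP × 20,000 lines; voluntary reformulation and
best-case mandatory reformulation carry no policy cost, only monitoring.

Benefits are averted national healthcare expenditures: 2019 inpatient CVD
expenditure (34,549 M USD) is assigned to the acute state and outpatient
expenditure (21,748 M USD) to the chronic state, divided by the baseline
occupancies to give fixed per-person-year unit costs (no unit-cost
inflation). The year-$t$ benefit prices the occupancy gap between the
no-intervention and the policy trajectory in both states. Costs and benefits
are discounted at 2%/yr under the end-of-cycle convention (first accrual at
$t = 1$, value divided by $1.02^{t}$); the convention is not stated by the
source framework, so the most common cohort-model default was adopted and
`discount_convention = "begin"` is available. No half-cycle correction is
applied to state occupancies. Net benefit is benefit minus cost; cumulative
series are running sums of discounted values.

## Parameters, provenance, placeholders

All parameters live in a single validated configuration
(`baseline_config()`), serialized to YAML and overridable file-by-file;
`flatten_config()` exports the flat parameter table with a `provenance`
column. Four quantities the model needs are not published in the primary
sources and ship as documented placeholders flagged `"not from paper"`:

| parameter | default | reasoning |
|---|---|---|
| annual acute case fatality | 0.10/yr | in-hospital/30-day CVD death of order 5–15% in high-income registries |
| annual chronic recurrence | 0.05/yr | secondary-event rates of a few percent per year |
| media-campaign policy cost (England scale) | 35 M GBP | order of a multi-year national media campaign |
| monitoring cost per decade (England scale) | 20 M GBP | 2 M GBP/yr programme monitoring |

These were fixed once, before any result was inspected, and every pipeline
run warns when they are in use. Because of them the package's monetary
totals are *not* expected to match the published headline figures — the
published model's exact transition probabilities and monitoring line items
are unavailable — and the tests therefore pin down exact analytic anchors
(the 0.2/1.5/2.0 annual rates, unit conversions, discount factors) and
structural properties (conservation, orderings, equalities) rather than
headline totals.

## Verification

The engine (`run_cohort()`, matrix algebra) is cross-checked against an
independently written scalar oracle (`oracle_run()`: explicit per-state
arithmetic, multipliers recomputed inline) to $10^{-9}$ relative error on 50
seeded, uniformly jittered parameter sets (±20%, resampled until all
invariants hold) across four policies — the central correctness property of
the repository. Conservation of the cohort total holds to floating tolerance
at every cycle; the dead pool is non-decreasing and the healthy pool
non-increasing by construction of the state diagram. With constant rates the
trajectory equals the initial vector times matrix powers. All test and
acceptance problem sizes (10 annual cycles, 50 perturbed configurations)
run in seconds.

## One-way sensitivity analysis

`tornado()` re-runs the cumulative net benefit with one parameter at a time
set to its bounds: discount rate 0–4%, the policy-effect ranges, and the 95%
CIs of CVD incidence, prevalence, mortality, and both relative risks, with
rates perturbed independently (one-way analysis by definition). Sweeps never
mutate the base configuration. On the packaged defaults the widest
net-benefit range belongs to the relative risk for CVD incidence, ahead of
the policy effect and the discount rate. This ordering is a structural
consequence of percent-per-gram risk scaling: the outcome is near-linear in
both the RR point estimate and the decade effect, so relative sweep widths
decide the ranking — the RR incidence CI (1–11 around 6) is relatively wider
than the reformulation effect ranges (10–32 around 20; 5–20 around 15),
while the discount sweep moves cumulative discounted values by only about a
quarter. A published tornado that places the policy effect first and the
discount rate ahead of the RR would require risk machinery (e.g. tabulated
cumulative risk reductions) beyond the percent-per-unit statement available
here.

## Known limitations

No sex/age stratification, no blood-pressure mediation step, no open cohort,
no QALYs/DALYs or productivity losses, no probabilistic sensitivity
analysis — the framework being reproduced is deterministic and
population-aggregate by design. The synthetic parameter-perturbation module
exercises code paths and invariants; it does not emulate sampling
variability of real surveillance data, so passing the property suite shows
internal correctness of the arithmetic, not calibration to any real
population.
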