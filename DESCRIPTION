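Package: saltsim
Title: Markov Cohort Simulation of Dietary Salt Reduction Policies and
    Cardiovascular Disease Costs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic Markov cohort macro-simulation of population-wide
    dietary salt (sodium) reduction policies and their effect on
    cardiovascular disease (CVD) burden and national healthcare expenditure.
    The model moves a closed national cohort among four mutually exclusive
    health states (healthy, acute CVD, chronic CVD, dead) in annual cycles;
    policy scenarios lower mean salt intake at a constant annual rate, which
    scales CVD incidence and case fatality through published relative risks.
    Intervention cost streams, averted-expenditure benefits, discounting,
    cumulative net benefit over a 10-year horizon, and deterministic one-way
    (tornado) sensitivity analyses are provided, together with a validated
    parameter data model, seeded synthetic parameter-set generation, and an
    independent brute-force simulation oracle for verification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
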