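Package: appmslt
Title: Multistate Life Table Cost-Effectiveness Modelling of Weight-Loss
    App Promotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A proportional multistate life table (MSLT) model for
    estimating the lifetime health gains (quality-adjusted life-years)
    and net health-system costs of a one-off mass-media campaign
    promoting smartphone apps for weight loss in a New Zealand-like
    population. The closed 2011 cohort, stratified by sex, ethnicity
    (Maori / non-Maori) and single year of age, is simulated to
    extinction alongside 14 body-mass-index related disease life tables
    (coronary heart disease, stroke, type 2 diabetes, osteoarthritis and
    ten cancers). Intervention uptake is modelled as a cascade
    (smartphone access, campaign exposure, app download, regular use),
    the resulting BMI change decays post-intervention and feeds
    population impact fractions that reduce disease inflow after
    disease-specific time lags. Includes a seeded synthetic baseline
    data generator, discounted QALY and cost accrual, ICERs, scenario
    grids, probabilistic sensitivity analysis with correlated parameter
    draws, and tornado uncertainty decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
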