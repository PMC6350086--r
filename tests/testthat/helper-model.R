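# Shared fixtures, built once per test session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

seed1_dataset <- function() memo("seed1_dataset", function() {
  generate_baseline(generator_config(), seed = 1)
})

base_profile <- function() memo("base_profile", function() {
  effect_profile(seed1_dataset())
})

base_run <- function() memo("base_run", function() {
  run_mslt(seed1_dataset(), base_profile())
})

base_result <- function() memo("base_result", function() {
  summarize_run(base_run(), seed1_dataset())
})

# Minimal hand-built dataset: flat mortality, optional diseases, one BMI band.
toy_dataset <- function(acm = 0.05, pyld = 0, base_cost = 1000,
                        diseases = list()) {
  ages <- 0:110
  gg <- expand.grid(sex = c("male", "female"),
                    ethnicity = c("maori", "non_maori"),
                    stringsAsFactors = FALSE)
  long <- function(value, col) {
    data.table::rbindlist(lapply(seq_len(4), function(g) {
      dt <- data.table::data.table(sex = gg$sex[g], ethnicity = gg$ethnicity[g],
                                   age = ages)
      dt[[col]] <- value
      dt
    }))
  }
  structure(list(
    base_year = 2011L,
    population = long(100, "count"),
    mortality = long(acm, "acm_rate"),
    pyld = long(pyld, "pyld_rate"),
    base_costs = data.table::rbindlist(lapply(c("male", "female"), function(s) {
      data.table::data.table(sex = s, age = ages, cost = base_cost)
    })),
    bmi = data.table::data.table(
      sex = rep(gg$sex, each = 1), ethnicity = gg$ethnicity,
      age_lo = 0L, age_hi = 110L, mean = 27, sd = 5),
    heights = data.table::data.table(sex = gg$sex, ethnicity = gg$ethnicity,
                                     mean = 1.7, sd = 0.07),
    overweight = long(0.6, "prop"),
    diseases = diseases,
    standard_population = appmslt:::who_standard_population(),
    config = list()
  ), class = "baseline_dataset")
}

# constant-rate disease table for toy datasets
toy_disease <- function(incidence, case_fatality, remission = 0, dr = 0.1,
                        rr = 1.1) {
  ages <- 0:110
  gg <- expand.grid(sex = c("male", "female"),
                    ethnicity = c("maori", "non_maori"),
                    stringsAsFactors = FALSE)
  data.table::rbindlist(lapply(seq_len(4), function(g) {
    data.table::data.table(
      age = ages, sex = gg$sex[g], ethnicity = gg$ethnicity[g],
      incidence = incidence, case_fatality = case_fatality,
      remission = remission, dr = dr, cost_first_year = 5000,
      cost_prevalent = 2000, cost_last6m = 10000, rr_per_unit = rr,
      trend_inc = 0, trend_cf = 0, trend_rem = 0)
  }))
}
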