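test_that("trends apply until 2026 and freeze afterwards", {
  expect_equal(trend_factor(0, 2019), 1)
  expect_equal(trend_factor(-0.02, 2013), 0.98^2)
  expect_equal(trend_factor(-0.02, 2040), trend_factor(-0.02, 2026))
  expect_error(trend_factor(0, 2005), "2011")

  spec <- toy_disease(0.01, 0.05)
  spec$trend_inc <- -0.02
  tr <- apply_trends(spec, 2013)
  expect_equal(tr$incidence, spec$incidence * 0.9604)
  expect_equal(tr$case_fatality, spec$case_fatality)
})

test_that("disease stepping follows the three-state difference equations", {
  st <- list(healthy = 0.9, prevalent = 0.1, dead = 0)
  rates <- list(incidence = 0.01, case_fatality = 0.1, remission = 0)
  nxt <- step_disease(st, rates)
  expect_equal(nxt$prevalent, 0.1 + 0.009 - 0.01)
  expect_equal(nxt$healthy, 0.9 - 0.009)
  expect_equal(nxt$dead, 0.01)
  expect_equal(nxt$healthy + nxt$prevalent + nxt$dead, 1)

  # a PIF of 1 fully averts inflow
  nxt1 <- step_disease(st, rates, pif = 1)
  expect_equal(nxt1$new_cases, 0)
  expect_equal(nxt1$healthy, st$healthy)

  bad <- list(healthy = 0.5, prevalent = 0.6, dead = 0)
  expect_error(step_disease(bad, list(incidence = 2, case_fatality = 0,
                                      remission = 0), label = "chd"),
               "chd")
})

test_that("long-run disease occupancy matches eigen-analysis of the transition matrix", {
  cases <- list(list(i = 0.02, f = 0, r = 0.05),   # dead unreachable
                list(i = 0.01, f = 0.02, r = 0.005),
                list(i = 0.004, f = 0.001, r = 0))
  for (cs in cases) {
    rates <- list(incidence = cs$i, case_fatality = cs$f, remission = cs$r)
    st <- list(healthy = 1, prevalent = 0, dead = 0)
    # the subdominant-to-dominant eigenvalue ratio governs convergence;
    # 12000 cycles suffice for the slowest case here
    for (k in 1:12000) st <- step_disease(st, rates)[c("healthy", "prevalent", "dead")]
    # transient sub-block of the 3-state transition matrix
    M <- matrix(c(1 - cs$i, cs$r,
                  cs$i, 1 - cs$f - cs$r), 2, 2, byrow = TRUE)
    ev <- eigen(M)
    v <- Re(ev$vectors[, which.max(Re(ev$values))])
    v <- v / sum(v)
    occ <- c(st$healthy, st$prevalent)
    if (sum(occ) > 1e-12) {
      expect_equal(occ / sum(occ), v, tolerance = 1e-6)
    }
    if (cs$f == 0) {
      # with no disease mortality the chain is the embedded two-state one
      # and prevalence converges to i/(i+f+r) exactly
      expect_equal(st$prevalent, cs$i / (cs$i + cs$f + cs$r), tolerance = 1e-9)
      expect_equal(st$dead, 0)
    }
  }
})

test_that("constant-mortality survival matches the geometric closed form", {
  m <- 0.05
  ds <- toy_dataset(acm = m)
  run <- run_mslt(ds, NULL)
  grid <- run$strata
  row <- which(grid$sex == "female" & grid$ethnicity == "non_maori" &
               grid$age0 == 0)
  T <- length(run$years)
  expect_equal(run$alive_bau[row, ], (1 - m)^(0:T), tolerance = 1e-12)
  le_model <- sum(run$ly_bau[row, ])
  le_closed <- sum(((1 - m)^(0:(T - 1)) + (1 - m)^(1:T)) / 2)
  expect_equal(le_model, le_closed, tolerance = 1e-6)
  # with no morbidity QALYs equal life-years
  expect_equal(run$qaly_bau[row, ], run$ly_bau[row, ])
})

test_that("QALY accrual down-weights life-years by morbidity", {
  ds <- toy_dataset(acm = 0.02, pyld = 0.12)
  run <- run_mslt(ds, NULL)
  expect_equal(run$qaly_bau, 0.88 * run$ly_bau, tolerance = 1e-12)
})

test_that("null intervention is bitwise identical across arms", {
  run <- run_mslt(seed1_dataset(), NULL)
  expect_identical(run$alive_bau, run$alive_int)
  expect_identical(run$qaly_bau, run$qaly_int)
  expect_identical(run$cost_bau, run$cost_int)
  zero_prof <- effect_profile(seed1_dataset(), uptake_cascade(p_download = 0))
  run0 <- run_mslt(seed1_dataset(), zero_prof)
  expect_identical(run0$qaly_bau, run0$qaly_int)
  expect_identical(run0$cost_bau, run0$cost_int)
})

test_that("disease-state conservation holds to 1e-9 over the full horizon", {
  run <- run_mslt(seed1_dataset(), base_profile(), keep_disease_tables = TRUE)
  for (dn in names(run$disease_tables)) {
    for (arm in c("bau", "int")) {
      tab <- run$disease_tables[[dn]][[arm]]
      drift <- abs(tab$healthy + tab$prevalent + tab$dead - 1)
      expect_lt(max(drift), 1e-9)
      expect_true(all(tab$healthy >= -1e-12 & tab$healthy <= 1 + 1e-12))
      expect_true(all(tab$prevalent >= -1e-12 & tab$prevalent <= 1 + 1e-12))
    }
  }
})

test_that("a BMI reduction with harmful RRs yields positive QALY gains", {
  run <- base_run()
  expect_gt(sum(run$qaly_int - run$qaly_bau), 0)
  # monotonicity: doubling the BMI change increases the gain
  ds <- seed1_dataset()
  p2 <- effect_profile(ds, effect = effect_size(-0.86))
  run2 <- run_mslt(ds, p2)
  expect_gt(sum(run2$qaly_int - run2$qaly_bau),
            sum(run$qaly_int - run$qaly_bau))
})

test_that("an effect restricted to Maori leaves non-Maori untouched", {
  ds <- seed1_dataset()
  prof <- base_profile()
  grid <- attr(prof, "strata")
  prof_m <- prof
  prof_m[grid$ethnicity != "maori", ] <- 0
  run <- run_mslt(ds, prof_m)
  nm <- grid$ethnicity == "non_maori"
  expect_identical(run$qaly_bau[nm, ], run$qaly_int[nm, ])
  expect_identical(run$cost_bau[nm, ], run$cost_int[nm, ])
  expect_gt(sum(run$qaly_int - run$qaly_bau), 0)
})

test_that("equity swap replaces Maori background rates and is idempotent", {
  ds <- seed1_dataset()
  sw <- equity_swap(ds)
  expect_identical(equity_swap(sw), sw)
  m <- sw$mortality
  wide <- merge(m[m$ethnicity == "maori", c("sex", "age", "acm_rate")],
                m[m$ethnicity == "non_maori", c("sex", "age", "acm_rate")],
                by = c("sex", "age"), suffixes = c("_ma", "_nm"))
  expect_equal(wide$acm_rate_ma, wide$acm_rate_nm)
  expect_identical(sw$diseases, ds$diseases)
  expect_identical(sw$population, ds$population)
})
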