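test_that("distribution fitting matches moments", {
  # gamma with 20% SD has shape 25: check mean and sd of a large sample
  g <- fit_distribution(list(name = "x", family = "gamma", central = 2883000,
                             sd = 576600, lo = NA, hi = NA,
                             lower = -Inf, upper = Inf))
  u <- withr::with_seed(1, runif(1e5))
  x <- g(u)
  expect_equal(mean(x), 2883000, tolerance = 0.01)
  expect_equal(sd(x), 576600, tolerance = 0.02)

  b <- fit_distribution(list(name = "x", family = "beta", central = 0.26,
                             sd = 0.052, lo = NA, hi = NA,
                             lower = -Inf, upper = Inf))
  xb <- b(u)
  expect_equal(mean(xb), 0.26, tolerance = 0.01)
  expect_equal(sd(xb), 0.052, tolerance = 0.02)
  expect_true(all(xb > 0 & xb < 1))

  unif <- fit_distribution(list(name = "x", family = "uniform", central = 0.5,
                                sd = NA, lo = 0, hi = 1,
                                lower = -Inf, upper = Inf))
  expect_equal(mean(unif(u)), 0.5, tolerance = 0.01)

  expect_error(fit_distribution(list(name = "x", family = "beta",
                                     central = 0.5, sd = 0.6, lo = NA, hi = NA,
                                     lower = -Inf, upper = Inf)),
               "infeasible")
})

test_that("a 95% interval implies sd = width/3.92", {
  specs <- default_parameter_specs()
  ek <- as.list(specs[specs$name == "effect_kg", ])
  expect_equal(appmslt:::spec_sd(ek), (0.61 - 0.25) / 3.92, tolerance = 1e-12)
})

test_that("copula sampling preserves marginals and the 0.75 rank correlation", {
  specs <- default_parameter_specs()
  X <- sample_parameters(specs, n = 1e4, seed = 3)
  X2 <- sample_parameters(specs, n = 1e4, seed = 3)
  expect_identical(X, X2)

  rho <- cor(X[, "intervention_cost"], X[, "p_download"], method = "spearman")
  expect_lt(abs(rho - 0.75), 0.03)
  rho2 <- cor(X[, "p_smartphone"], X[, "p_exposed"], method = "spearman")
  expect_lt(abs(rho2 - 0.75), 0.03)
  # parameters outside the correlation group stay independent
  rho3 <- cor(X[, "effect_kg"], X[, "p_download"], method = "spearman")
  expect_lt(abs(rho3), 0.05)
  rho4 <- cor(X[, "decay_rate"], X[, "pyld_mult"], method = "spearman")
  expect_lt(abs(rho4), 0.05)

  # marginal preservation within 2%
  expect_equal(mean(X[, "p_regular_use"]), 0.26, tolerance = 0.02)
  expect_equal(sd(X[, "p_regular_use"]), 0.052, tolerance = 0.05)
  expect_equal(mean(X[, "intervention_cost"]), 2883000, tolerance = 0.02)
  # effect size draws are truncated at zero (no harmful draws)
  expect_true(all(X[, "effect_kg"] <= 0))
})

test_that("degenerate PSA reproduces the expected-value run exactly", {
  ds <- seed1_dataset()
  specs <- default_parameter_specs()
  specs <- data.table::copy(specs)
  specs$sd <- 0
  specs$lo <- NA_real_
  specs$hi <- NA_real_
  specs$family[specs$family == "uniform"] <- "normal"
  psa <- run_psa(ds, scenario(), specs, n = 3L, seed = 5)
  central <- run_scenario(ds, scenario())
  expect_equal(psa$draws$delta_qalys, rep(central$delta_qalys, 3))
  expect_equal(psa$draws$net_cost_nzd, rep(central$net_cost_nzd, 3))
  expect_equal(psa$rejected, 0L)
})

test_that("PSA summarises draws with percentile uncertainty intervals", {
  ds <- seed1_dataset()
  psa <- run_psa(ds, scenario(), n = 30L, seed = 9)
  expect_equal(nrow(psa$draws), 30L)
  expect_lte(psa$ui_qalys[1], psa$median_qalys)
  expect_lte(psa$median_qalys, psa$ui_qalys[2])
  expect_lte(psa$ui_cost[1], psa$ui_cost[2])
  expect_true(psa$prob_cost_effective >= 0 && psa$prob_cost_effective <= 1)
  # PSA mean should be in the neighbourhood of the expected-value run
  central <- run_scenario(ds, scenario())
  se <- sd(psa$draws$delta_qalys) / sqrt(30)
  expect_lt(abs(psa$mean_qalys - central$delta_qalys),
            max(4 * se, 0.5 * central$delta_qalys))
})

test_that("tornado spans are non-negative and zero-width groups rank last", {
  ds <- seed1_dataset()
  specs <- data.table::copy(default_parameter_specs())
  # make the decay group zero-width to pin the ranking
  specs$sd[specs$group == "bmi_decay"] <- 0
  tor <- tornado(ds, scenario(), specs,
                 groups = c("effect_size", "bmi_decay"), n = 30L, seed = 4)
  expect_true(all(tor$qaly_span >= 0))
  expect_equal(tor$qaly_span[tor$group == "bmi_decay"], 0)
  expect_equal(tor$rank_qaly[tor$group == "bmi_decay"], 2L)
  expect_equal(tor$rank_qaly[tor$group == "effect_size"], 1L)
  expect_error(tornado(ds, scenario(), specs, groups = "nope", n = 2L),
               "unknown tornado group")
})
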