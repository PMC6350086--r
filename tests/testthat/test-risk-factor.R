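test_that("relative risk follows the per-unit exponential form", {
  rf <- risk_function(1.1, tmrel = 21)
  expect_equal(relative_risk(21, rf), 1)
  expect_equal(relative_risk(15, rf), 1)
  expect_equal(relative_risk(22, rf), 1.1)
  expect_equal(relative_risk(30, rf), 1.1^9)
  bmis <- seq(15, 45, by = 0.5)
  expect_true(all(diff(relative_risk(bmis, rf)) >= 0))
  expect_error(relative_risk(0, rf), "positive")
  expect_error(relative_risk(-3, rf), "positive")
  expect_error(risk_function(0.9), ">= 1")
})

test_that("pif closed-form and degenerate cases", {
  rf <- risk_function(1.1, tmrel = 21)
  base <- bmi_distribution(28, 5)
  expect_equal(pif(base, base, rf), 0)
  flat <- risk_function(1, tmrel = 21)
  expect_equal(pif(base, shift_distribution(base, -2), flat), 0)
  # point mass at 30 shifted to 29: 1 - 1.1^8/1.1^9
  pm <- bmi_distribution(30, family = "point")
  expect_equal(pif(pm, shift_distribution(pm, -1), rf), 1 - 1 / 1.1,
               tolerance = 1e-12)
})

test_that("pif is monotone in shift size and sign-antisymmetric", {
  rf <- risk_function(1.08, tmrel = 21)
  base <- bmi_distribution(29, 4.5)
  shifts <- c(-0.05, -0.2, -0.5, -1, -2)
  vals <- vapply(shifts, function(s) pif(base, shift_distribution(base, s), rf),
                 numeric(1))
  expect_true(all(diff(vals) > 0))  # larger leftward shift, larger PIF
  expect_true(all(vals > 0 & vals < 1))
  up <- pif(base, shift_distribution(base, 0.5), rf)
  dn <- pif(base, shift_distribution(base, -0.5), rf)
  expect_lt(up, 0)
  expect_gt(dn, 0)
})

test_that("adaptive-integration pif agrees with Monte Carlo", {
  set.seed(42)
  for (k in 1:5) {
    m <- runif(1, 25, 31); s <- runif(1, 3.5, 6)
    rr <- runif(1, 1.03, 1.15); tm <- runif(1, 20, 23)
    delta <- -runif(1, 0.05, 0.6)
    rf <- risk_function(rr, tm)
    base <- bmi_distribution(m, s)
    p_int <- pif(base, shift_distribution(base, delta), rf)
    lp <- appmslt:::lnorm_params(m, s)
    x <- rlnorm(2e5, lp$meanlog, lp$sdlog)
    rr_b <- relative_risk(x, rf); rr_s <- relative_risk(x + delta, rf)
    p_mc <- 1 - mean(rr_s) / mean(rr_b)
    resid <- rr_s - (1 - p_mc) * rr_b
    se <- sd(resid) / mean(rr_b) / sqrt(length(x))
    expect_lt(abs(p_int - p_mc), 3 * se + 1e-10)
  }
})

test_that("engine quadrature PIF matches the adaptive-integration backend", {
  ds <- seed1_dataset()
  nodes <- appmslt:::build_bmi_nodes(ds)
  grid <- strata_grid()
  gi <- appmslt:::group_index(grid$sex, grid$ethnicity)
  amat <- vapply(seq_len(111), function(t) pmin(grid$age0 + t - 1L, 110L),
                 integer(444))
  dm <- appmslt:::disease_matrices(ds$diseases$diabetes)
  dl <- matrix(0, 444, 111)
  dl[, 3] <- -0.02
  pm <- appmslt:::pif_matrix(dl, dm, nodes, 21, amat, gi)
  for (row in c(60, 200, 400)) {
    age <- amat[row, 3]
    if (age < 25) next
    band <- ds$bmi[appmslt:::group_index(ds$bmi$sex, ds$bmi$ethnicity) == gi[row] &
                   ds$bmi$age_lo <= age & ds$bmi$age_hi >= age, ]
    rf <- risk_function(dm$rr[gi[row], age + 1], 21)
    base <- bmi_distribution(band$mean, band$sd)
    expect_equal(pm[row, 3],
                 pif(base, shift_distribution(base, -0.02), rf),
                 tolerance = 1e-6)
  }
})

test_that("lagged BMI change averages the window with zero padding", {
  w05 <- lag_window(0, 5)
  expect_equal(lagged_delta_bmi(rep(0, 40), 7, w05), 0)
  pulse <- c(-0.15, rep(0, 39))
  expect_equal(lagged_delta_bmi(pulse, 0, w05), -0.15 / 6)
  expect_equal(lagged_delta_bmi(pulse, 5, w05), -0.15 / 6)
  expect_equal(lagged_delta_bmi(pulse, 6, w05), 0)
  w1030 <- lag_window(10, 30)
  expect_equal(lagged_delta_bmi(pulse, 5, w1030), 0)
  expect_equal(lagged_delta_bmi(pulse, 10, w1030), -0.15 / 21)
  expect_error(lag_window(5, 5), "lower < upper")
  expect_error(lag_window(-1, 5), "lower")
})

test_that("lagged mean is bounded by the history's extreme values", {
  set.seed(7)
  for (k in 1:20) {
    h <- -runif(30, 0, 0.3)
    w <- lag_window(sample(0:10, 1), sample(11:35, 1))
    y <- sample(0:40, 1)
    v <- lagged_delta_bmi(h, y, w)
    expect_gte(v, min(c(h, 0)))
    expect_lte(v, max(c(h, 0)))
  }
})

test_that("decay profile regains monthly and never overshoots", {
  dur <- decay_duration_months(-0.155, decay_model(0.03))
  expect_equal(dur, 5)
  prof <- decay_profile(-0.155, decay_model(0.03), horizon = 5)
  expect_equal(prof[1], -0.155)
  expect_true(all(prof <= 0))
  expect_equal(prof[3], 0)  # fully decayed by year 3

  expect_equal(decay_profile(-0.2, decay_model(0, enabled = TRUE), 4),
               rep(-0.2, 4))
  expect_equal(decay_profile(-0.2, decay_model(0.03, enabled = FALSE), 4),
               rep(-0.2, 4))

  # explicit monthly enumeration oracle for year 2
  prof2 <- decay_profile(-0.36, decay_model(0.03), horizon = 3)
  expect_equal(prof2[2], mean(pmin(0, -0.36 + 0.03 * (1:12))))
  expect_equal(prof2[3], mean(pmin(0, -0.36 + 0.03 * (13:24))))
  expect_error(decay_profile(0.1, decay_model(), 5), "<= 0")
  expect_error(decay_profile(-0.1, decay_model(), 0), "horizon")
})
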