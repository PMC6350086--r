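#' Default settings for the synthetic baseline generator
#'
#' The generator emulates the structure of the New Zealand-like baseline the
#' model needs: a closed 2011 cohort of about 4.4 million people, a Maori
#' population share of about 15%, Gompertz-Makeham all-cause mortality with a
#' Maori hazard multiplier (so the equity analysis is non-trivial), log-normal
#' BMI distributions by sex, ethnicity and age band, and 14 coherent
#' BMI-related disease rate tables.
#'
#' @param total_population Total cohort size across all strata.
#' @param maori_share Proportion of the cohort that is Maori.
#' @param maori_mortality_multiplier Hazard multiplier applied to Maori
#'   all-cause mortality (and, attenuated, to morbidity and disease rates).
#' @param gompertz Named list with Makeham constant `makeham`, slope `b` and
#'   level `a` of the Gompertz term (annual probabilities).
#' @param rate_noise_sd Log-scale SD of the seeded multiplicative noise put on
#'   disease incidence and case fatality (gives each seed its own dataset).
#' @param bmi_maori_shift Additive shift of mean BMI for Maori strata.
#' @return A list of generator settings, class `mslt_generator_config`.
#' @export
generator_config <- function(total_population = 4.4e6,
                             maori_share = 0.15,
                             maori_mortality_multiplier = 1.6,
                             gompertz = list(makeham = 4e-4, a = 2.2e-5, b = 0.095),
                             rate_noise_sd = 0.03,
                             bmi_maori_shift = 1.8) {
  if (!is.numeric(total_population) || total_population <= 0) {
    stop("total_population must be positive")
  }
  if (!is.numeric(maori_share) || maori_share <= 0 || maori_share > 1) {
    stop("maori_share must be in (0, 1]")
  }
  structure(list(
    total_population = total_population,
    maori_share = maori_share,
    maori_mortality_multiplier = maori_mortality_multiplier,
    gompertz = gompertz,
    rate_noise_sd = rate_noise_sd,
    bmi_maori_shift = bmi_maori_shift
  ), class = "mslt_generator_config")
}

DISEASE_NAMES <- c("chd", "stroke", "diabetes", "osteoarthritis",
                   "endometrial_ca", "kidney_ca", "liver_ca", "esophageal_ca",
                   "pancreatic_ca", "thyroid_ca", "colorectal_ca", "breast_ca",
                   "ovarian_ca", "gallbladder_ca")

#' @export
disease_group <- function(name) {
  ifelse(grepl("_ca$", name), "cancer", "noncancer")
}

# Disease rate templates as smooth functions of age. Cancers carry a 5-year
# case-fatality risk F5; the annual case fatality and remission split the
# 1/5-per-year exit so that the absorption probability into death equals F5
# and remission is its complement (expected 5-year relative survival).
disease_templates <- function() {
  rise <- function(age, base, slope, start, cap) {
    pmin(cap, ifelse(age >= start, base * exp(slope * (age - start)), 0))
  }
  peak <- function(age, height, centre, width, start) {
    ifelse(age >= start, height * exp(-((age - centre) / width)^2), 0)
  }
  cancer <- function(base, slope, start, f5, rr, cost1, costp, cost6, dr,
                     female_only = FALSE, male_factor = 1) {
    list(group = "cancer",
         inc = function(age, male) {
           sf <- if (female_only) ifelse(male, 0, 1) else ifelse(male, male_factor, 1)
           sf * rise(age, base, slope, start, cap = 0.01)
         },
         cf = function(age, male) rep(f5 / 5, length(age)),
         rem = function(age, male) rep((1 - f5) / 5, length(age)),
         rr = rr, dr = dr,
         cost_first_year = cost1, cost_prevalent = costp, cost_last6m = cost6,
         trend_inc = -0.003, trend_cf = -0.015, trend_rem = 0.005)
  }
  list(
    chd = list(group = "noncancer",
      inc = function(age, male) ifelse(male, 1.5, 1) * rise(age, 1.5e-4, 0.08, 40, 0.05),
      cf = function(age, male) rise(age, 0.03, 0.03, 40, 0.4),
      rem = function(age, male) rep(0, length(age)),
      rr = 1.06, dr = 0.08,
      cost_first_year = 18000, cost_prevalent = 8000, cost_last6m = 20000,
      trend_inc = -0.02, trend_cf = -0.025, trend_rem = 0),
    stroke = list(group = "noncancer",
      inc = function(age, male) ifelse(male, 1.2, 1) * rise(age, 8e-5, 0.085, 45, 0.04),
      cf = function(age, male) rise(age, 0.05, 0.03, 45, 0.45),
      rem = function(age, male) rep(0, length(age)),
      rr = 1.05, dr = 0.18,
      cost_first_year = 22000, cost_prevalent = 12000, cost_last6m = 22000,
      trend_inc = -0.015, trend_cf = -0.02, trend_rem = 0),
    diabetes = list(group = "noncancer",
      inc = function(age, male) peak(age, 0.006, 58, 18, 18),
      cf = function(age, male) pmin(0.15, 0.03 * exp(0.01 * (age - 40))),
      rem = function(age, male) rep(0, length(age)),
      rr = 1.18, dr = 0.06,
      cost_first_year = 8000, cost_prevalent = 7000, cost_last6m = 15000,
      trend_inc = 0.01, trend_cf = -0.01, trend_rem = 0),
    osteoarthritis = list(group = "noncancer",
      inc = function(age, male) ifelse(age >= 25, 0.004 / (1 + exp(-(age - 55) / 8)), 0),
      cf = function(age, male) 0.01 + 0.008 / (1 + exp(-(age - 70) / 8)),
      rem = function(age, male) rep(0, length(age)),
      rr = 1.05, dr = 0.12,
      cost_first_year = 6000, cost_prevalent = 5000, cost_last6m = 8000,
      trend_inc = 0, trend_cf = 0, trend_rem = 0),
    endometrial_ca = cancer(2.5e-5, 0.09, 40, 0.20, 1.12, 35000, 12000, 30000, 0.15, female_only = TRUE),
    kidney_ca = cancer(1.5e-5, 0.09, 40, 0.35, 1.06, 35000, 12000, 30000, 0.18, male_factor = 1.6),
    liver_ca = cancer(8e-6, 0.09, 40, 0.80, 1.05, 38000, 14000, 32000, 0.30, male_factor = 2),
    esophageal_ca = cancer(8e-6, 0.09, 45, 0.80, 1.09, 38000, 14000, 32000, 0.30, male_factor = 2.2),
    pancreatic_ca = cancer(1.2e-5, 0.09, 45, 0.90, 1.03, 40000, 14000, 34000, 0.35, male_factor = 1.2),
    thyroid_ca = cancer(1.5e-5, 0.04, 25, 0.05, 1.02, 20000, 8000, 24000, 0.10, male_factor = 0.4),
    colorectal_ca = cancer(6e-5, 0.09, 40, 0.35, 1.03, 35000, 12000, 30000, 0.20, male_factor = 1.1),
    breast_ca = cancer(1.2e-4, 0.05, 30, 0.12, 1.02, 32000, 10000, 28000, 0.15, male_factor = 0.01),
    ovarian_ca = cancer(2e-5, 0.08, 40, 0.55, 1.02, 36000, 12000, 31000, 0.22, female_only = TRUE),
    gallbladder_ca = cancer(5e-6, 0.09, 45, 0.70, 1.06, 36000, 12000, 31000, 0.25, male_factor = 0.7)
  )
}

# Piecewise-linear mean BMI by age (non-Maori); right-skew handled by the
# log-normal family downstream.
bmi_mean_curve <- function(age) {
  knots_age <- c(0, 10, 20, 35, 50, 65, 80, 110)
  knots_val <- c(16, 17.5, 25.5, 27.5, 28.5, 28.8, 27.5, 26)
  stats::approx(knots_age, knots_val, xout = age, rule = 2)$y
}

who_standard_population <- function() {
  # WHO World Standard Population weights, 5-year bands, 85+ pooled.
  w <- c(8.86, 8.69, 8.60, 8.47, 8.22, 7.93, 7.61, 7.15, 6.59, 6.04,
         5.37, 4.55, 3.72, 2.96, 2.21, 1.52, 0.91, 0.63)
  data.table(age_lo = seq(0L, 85L, 5L),
             age_hi = c(seq(4L, 84L, 5L), MAX_AGE),
             weight = w / sum(w))
}

#' Generate a synthetic NZ-like baseline dataset
#'
#' Builds every business-as-usual input the multistate life table needs:
#' stratum population counts, all-cause mortality, prevalent-YLD morbidity,
#' baseline health-system costs, BMI and height distributions,
#' overweight/obese prevalence, a standard population for age
#' standardisation, and one coherent incidence/case-fatality/remission rate
#' table per disease (with trends, disability rates, staged costs and
#' relative risks per BMI unit).
#'
#' The same `seed` and `config` always reproduce the identical dataset, and
#' every generated dataset passes [coherence_check()] with zero violations:
#' case fatalities are rescaled (deterministically, as part of generation) so
#' that expected disease deaths never exceed half the all-cause mortality in
#' any stratum.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return A `baseline_dataset` object (a list of `data.table`s).
#' @export
#' @examples
#' ds <- generate_baseline(generator_config(total_population = 1e5), seed = 1)
#' sum(ds$population$count)
generate_baseline <- function(config = generator_config(), seed = 1L) {
  if (!inherits(config, "mslt_generator_config")) {
    stop("config must be created by generator_config()")
  }
  with_seed(seed, build_baseline(config))
}

build_baseline <- function(cfg) {
  ages <- 0:MAX_AGE
  gg <- group_grid() # 4 rows: sex x ethnicity
  male <- gg$sex == "male"
  maori <- gg$ethnicity == "maori"

  ## population counts: Maori age structure younger than non-Maori
  taper <- function(age, start, width) exp(-pmax(0, age - start)^2 / (2 * width^2))
  pop <- data.table::rbindlist(lapply(seq_len(4L), function(g) {
    w <- if (maori[g]) taper(ages, 30, 16) else taper(ages, 45, 20)
    w <- w * (1 + 0.01 * rnorm(length(w)))
    share <- if (maori[g]) cfg$maori_share else 1 - cfg$maori_share
    counts <- round(cfg$total_population * share * 0.5 * w / sum(w))
    data.table(sex = gg$sex[g], ethnicity = gg$ethnicity[g], age = ages,
               count = as.numeric(counts))
  }))

  ## all-cause mortality: Gompertz-Makeham + infant bump, closed at age 110
  gp <- cfg$gompertz
  mort <- data.table::rbindlist(lapply(seq_len(4L), function(g) {
    mult <- ifelse(male[g], 1.35, 1) * ifelse(maori[g], cfg$maori_mortality_multiplier, 1)
    h <- mult * (gp$makeham + gp$a * exp(gp$b * ages) + 0.004 * exp(-ages))
    h <- pmin(h, 0.95)
    h[ages == MAX_AGE] <- 1
    data.table(sex = gg$sex[g], ethnicity = gg$ethnicity[g], age = ages,
               acm_rate = h)
  }))

  ## prevalent YLD per capita
  pyld <- data.table::rbindlist(lapply(seq_len(4L), function(g) {
    mult <- ifelse(male[g], 0.95, 1) * ifelse(maori[g], 1.35, 1)
    data.table(sex = gg$sex[g], ethnicity = gg$ethnicity[g], age = ages,
               pyld_rate = pmin(0.9, mult * (0.02 + 0.13 * (ages / 100)^2.5)))
  }))

  ## baseline health-system cost, sex x age (NZ$ 2011)
  base_costs <- data.table::rbindlist(lapply(SEXES, function(s) {
    mult <- if (s == "female") 1.08 else 1
    data.table(sex = s, age = ages,
               cost = mult * (1500 + 2000 * exp(-ages / 2) + 6000 * (ages / 100)^3))
  }))

  ## BMI distributions on 5-year bands; overweight prevalence derived from
  ## the same log-normal so the cascade and PIF stages stay consistent
  band_lo <- seq(0L, 105L, 5L)
  bmi <- data.table::rbindlist(lapply(seq_len(4L), function(g) {
    mid <- pmin(band_lo + 2.5, MAX_AGE)
    m <- bmi_mean_curve(mid) + if (maori[g]) cfg$bmi_maori_shift else 0
    data.table(sex = gg$sex[g], ethnicity = gg$ethnicity[g],
               age_lo = band_lo, age_hi = c(band_lo[-1] - 1L, MAX_AGE),
               mean = m, sd = pmax(2.5, 0.17 * m))
  }))

  heights <- data.table(
    sex = gg$sex, ethnicity = gg$ethnicity,
    mean = ifelse(male, ifelse(maori, 1.74, 1.76), ifelse(maori, 1.61, 1.62)),
    sd = 0.07
  )

  overweight <- data.table::rbindlist(lapply(seq_len(4L), function(g) {
    bg <- bmi[group_index(bmi$sex, bmi$ethnicity) == g]
    band <- findInterval(ages, bg$age_lo)
    lp <- lnorm_params(bg$mean[band], bg$sd[band])
    data.table(sex = gg$sex[g], ethnicity = gg$ethnicity[g], age = ages,
               prop = 1 - plnorm(25, lp$meanlog, lp$sdlog))
  }))

  ## disease rate tables
  tmpl <- disease_templates()
  diseases <- lapply(DISEASE_NAMES, function(dn) {
    tp <- tmpl[[dn]]
    data.table::rbindlist(lapply(seq_len(4L), function(g) {
      eth_mult <- if (maori[g]) 1.3 else 1
      inc <- pmin(1, eth_mult * tp$inc(ages, male[g]) *
                    exp(rnorm(length(ages), 0, cfg$rate_noise_sd)))
      cf <- pmin(1, tp$cf(ages, male[g]) *
                   exp(rnorm(length(ages), 0, cfg$rate_noise_sd)))
      rem <- pmin(1, tp$rem(ages, male[g]))
      data.table(age = ages, sex = gg$sex[g], ethnicity = gg$ethnicity[g],
                 incidence = inc, case_fatality = cf, remission = rem,
                 dr = tp$dr, cost_first_year = tp$cost_first_year,
                 cost_prevalent = tp$cost_prevalent, cost_last6m = tp$cost_last6m,
                 rr_per_unit = tp$rr, trend_inc = tp$trend_inc,
                 trend_cf = tp$trend_cf, trend_rem = tp$trend_rem)
    }))
  })
  names(diseases) <- DISEASE_NAMES

  ds <- structure(list(
    base_year = BASE_YEAR,
    population = pop, mortality = mort, pyld = pyld, base_costs = base_costs,
    bmi = bmi, heights = heights, overweight = overweight,
    diseases = diseases, standard_population = who_standard_population(),
    config = unclass(cfg)
  ), class = "baseline_dataset")

  rescale_case_fatalities(ds)
}

# arithmetic mean/sd -> log-normal parameters
lnorm_params <- function(mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Steady-state prevalence of the embedded healthy<->prevalent chain.
steady_prevalence <- function(incidence, case_fatality, remission) {
  denom <- incidence + case_fatality + remission
  ifelse(denom > 0, incidence / denom, 0)
}

# Cap total expected disease deaths at half of all-cause mortality in every
# (sex, ethnicity, age) cell by scaling case fatalities down. cf*prev is
# monotone increasing in cf, so a couple of fixed-point passes converge.
rescale_case_fatalities <- function(ds, share = 0.5, passes = 4L) {
  acm <- group_age_matrix(ds$mortality, "acm_rate")
  for (pass in seq_len(passes)) {
    total <- matrix(0, 4L, MAX_AGE + 1L)
    for (dn in names(ds$diseases)) {
      d <- ds$diseases[[dn]]
      prev <- steady_prevalence(d$incidence, d$case_fatality, d$remission)
      gi <- group_index(d$sex, d$ethnicity)
      total[cbind(gi, d$age + 1L)] <- total[cbind(gi, d$age + 1L)] +
        d$case_fatality * prev
    }
    s <- ifelse(total > share * acm, share * acm / total, 1)
    if (all(s >= 1 - 1e-12)) break
    for (dn in names(ds$diseases)) {
      d <- ds$diseases[[dn]]
      gi <- group_index(d$sex, d$ethnicity)
      ds$diseases[[dn]]$case_fatality <- d$case_fatality * s[cbind(gi, d$age + 1L)]
    }
  }
  ds
}

#' Check a baseline dataset for epidemiological coherence
#'
#' Verifies that the rate tables form a coherent set: all rates and
#' proportions are probabilities, noncancer remission is zero, expected
#' disease deaths (case fatality times steady-state prevalence, summed over
#' diseases) never exceed all-cause mortality, and the initial prevalence the
#' model derives from each disease's rates balances the embedded
#' healthy/prevalent chain within a relative tolerance.
#'
#' @param ds A `baseline_dataset`.
#' @param tol Relative tolerance for the steady-state balance check.
#' @return A character vector of violation messages; empty when coherent.
#' @export
coherence_check <- function(ds, tol = 0.25) {
  violations <- character()
  rate_cols <- c("incidence", "case_fatality", "remission")
  for (dn in names(ds$diseases)) {
    d <- ds$diseases[[dn]]
    for (cl in rate_cols) {
      bad <- d[[cl]] < 0 | d[[cl]] > 1
      if (any(bad)) {
        violations <- c(violations, sprintf(
          "rate out of range: %s %s at %d cell(s)", dn, cl, sum(bad)))
      }
    }
    if (disease_group(dn) == "noncancer" && any(d$remission != 0)) {
      violations <- c(violations, sprintf("noncancer remission nonzero: %s", dn))
    }
  }
  if (any(ds$mortality$acm_rate < 0 | ds$mortality$acm_rate > 1)) {
    violations <- c(violations, "rate out of range: acm_rate")
  }
  if (any(ds$overweight$prop < 0 | ds$overweight$prop > 1)) {
    violations <- c(violations, "rate out of range: overweight prop")
  }
  if (any(ds$population$count < 0)) {
    violations <- c(violations, "negative population count")
  }
  if (any(ds$pyld$pyld_rate < 0)) {
    violations <- c(violations, "negative pyld rate")
  }
  if (any(ds$bmi$sd <= 0)) violations <- c(violations, "bmi sd not positive")
  if (any(ds$heights$mean < 1.4 | ds$heights$mean > 2.0)) {
    violations <- c(violations, "height mean outside [1.4, 2.0] m")
  }

  ## disease deaths vs all-cause mortality
  acm <- group_age_matrix(ds$mortality, "acm_rate")
  total <- matrix(0, 4L, MAX_AGE + 1L)
  for (dn in names(ds$diseases)) {
    d <- ds$diseases[[dn]]
    prev <- steady_prevalence(d$incidence, d$case_fatality, d$remission)
    gi <- group_index(d$sex, d$ethnicity)
    total[cbind(gi, d$age + 1L)] <- total[cbind(gi, d$age + 1L)] +
      d$case_fatality * prev
  }
  over <- which(total > acm + 1e-12, arr.ind = TRUE)
  if (nrow(over) > 0) {
    gg <- group_grid()
    for (k in seq_len(min(nrow(over), 5L))) {
      violations <- c(violations, sprintf(
        "disease deaths exceed all-cause mortality: sex=%s ethnicity=%s age=%d",
        gg$sex[over[k, 1]], gg$ethnicity[over[k, 1]], over[k, 2] - 1L))
    }
    if (nrow(over) > 5L) {
      violations <- c(violations, sprintf("... and %d more cells", nrow(over) - 5L))
    }
  }

  ## one-step balance of the embedded chain at the derived prevalence
  for (dn in names(ds$diseases)) {
    d <- ds$diseases[[dn]]
    p0 <- steady_prevalence(d$incidence, d$case_fatality, d$remission)
    inflow <- (1 - p0) * d$incidence
    outflow <- p0 * (d$case_fatality + d$remission)
    imbalance <- abs(inflow - outflow)
    bad <- imbalance > tol * pmax(inflow, outflow) + 1e-12
    if (any(bad)) {
      violations <- c(violations, sprintf(
        "prevalence inconsistent with steady state: %s at %d cell(s)",
        dn, sum(bad)))
    }
  }
  violations
}

#' @export
print.baseline_dataset <- function(x, ...) {
  cat("<baseline_dataset>\n")
  cat("  base year:", x$base_year, "\n")
  cat("  strata:", nrow(strata_grid()), " (2 sex x 2 ethnicity x 111 ages)\n")
  cat("  total population:", format(sum(x$population$count), big.mark = ","), "\n")
  maori <- x$population$ethnicity == "maori"
  cat(sprintf("  Maori share: %.3f\n",
              sum(x$population$count[maori]) / sum(x$population$count)))
  cat("  diseases:", length(x$diseases), paste0("(", paste(names(x$diseases)[1:4],
      collapse = ", "), ", ...)"), "\n")
  invisible(x)
}
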