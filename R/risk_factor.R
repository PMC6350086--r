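#' Relative-risk function for BMI
#'
#' The exposure-response takes the standard comparative-risk-assessment form:
#' relative risk multiplies by `rr_per_unit` for every BMI unit above the
#' theoretical minimum risk exposure level (TMREL) and is 1 at or below it,
#' so `RR(b) = rr_per_unit^max(0, b - tmrel)`.
#'
#' Risk is taken flat above an exposure cap (BMI 60 by default): the
#' exponential form is not meant to extrapolate to implausible exposures,
#' and without a plateau the expectation of RR under a log-normal exposure
#' distribution would diverge (the log-normal has no moment generating
#' function).
#'
#' @param rr_per_unit Relative risk per BMI unit above the TMREL (>= 1 for
#'   the harmful exposures modelled here).
#' @param tmrel Theoretical minimum risk exposure level, BMI units.
#' @param cap Exposure level above which risk stops increasing.
#' @return An object of class `risk_function`.
#' @export
risk_function <- function(rr_per_unit, tmrel = 21, cap = 60) {
  stopifnot(is.numeric(rr_per_unit), length(rr_per_unit) == 1L,
            is.numeric(tmrel), length(tmrel) == 1L)
  if (rr_per_unit < 1) stop("rr_per_unit must be >= 1")
  if (cap <= tmrel) stop("cap must exceed tmrel")
  structure(list(rr_per_unit = rr_per_unit, tmrel = tmrel, cap = cap),
            class = "risk_function")
}

#' @param bmi BMI value(s), units kg/m^2; must be positive.
#' @param rf A [risk_function()].
#' @rdname risk_function
#' @export
relative_risk <- function(bmi, rf) {
  if (any(bmi <= 0)) stop("bmi must be positive")
  rf$rr_per_unit^pmax(0, pmin(bmi, rf$cap) - rf$tmrel)
}

#' BMI distribution objects
#'
#' Continuous stratum BMI is modelled log-normal (right-skewed, as adult BMI
#' data are), parameterised by its arithmetic mean and SD; a degenerate
#' point-mass is available for closed-form checks. An intervention shifts the
#' distribution by a location change with shape preserved.
#'
#' @param mean Arithmetic mean BMI (or the point-mass location).
#' @param sd Arithmetic SD; ignored for `family = "point"`.
#' @param family `"lognormal"`, `"normal"` or `"point"`.
#' @param shift Location shift in BMI units (negative = weight loss).
#' @export
bmi_distribution <- function(mean, sd = 0, family = c("lognormal", "normal", "point"),
                             shift = 0) {
  family <- match.arg(family)
  if (family != "point" && sd <= 0) stop("sd must be positive")
  structure(list(mean = mean, sd = sd, family = family, shift = shift),
            class = "bmi_distribution")
}

#' @param dist A [bmi_distribution()].
#' @rdname bmi_distribution
#' @export
shift_distribution <- function(dist, shift) {
  dist$shift <- dist$shift + shift
  dist
}

# log-density of the unshifted parent evaluated at x - shift
dist_log_density <- function(dist) {
  if (dist$family == "lognormal") {
    lp <- lnorm_params(dist$mean, dist$sd)
    function(x) dlnorm(x - dist$shift, lp$meanlog, lp$sdlog, log = TRUE)
  } else {
    function(x) dnorm(x - dist$shift, dist$mean, dist$sd, log = TRUE)
  }
}

dist_expect_rr <- function(dist, rf, rel.tol = 1e-8) {
  if (dist$family == "point") {
    return(relative_risk(max(dist$mean + dist$shift, 1e-12), rf))
  }
  ld <- dist_log_density(dist)
  # the density decays faster than the exponential RR grows; evaluating in
  # log space avoids Inf * 0 in the far tail
  f <- function(x) {
    exp(ld(x) + log(rf$rr_per_unit) * pmax(0, pmin(x, rf$cap) - rf$tmrel))
  }
  # split at the TMREL and cap kinks so the adaptive rule converges cleanly
  lo <- integrate(f, -Inf, rf$tmrel, rel.tol = rel.tol, abs.tol = 0,
                  subdivisions = 400L)
  mid <- integrate(f, rf$tmrel, rf$cap, rel.tol = rel.tol, abs.tol = 0,
                   subdivisions = 400L)
  hi <- integrate(f, rf$cap, Inf, rel.tol = rel.tol, abs.tol = 1e-14,
                  subdivisions = 400L)
  msgs <- c(lo$message, mid$message, hi$message)
  if (any(msgs != "OK")) {
    stop("PIF integral did not converge: ", paste(msgs, collapse = " / "))
  }
  lo$value + mid$value + hi$value
}

#' Population impact fraction over continuous BMI distributions
#'
#' `PIF = 1 - E_shifted[RR(X)] / E_baseline[RR(X)]`, the proportional
#' reduction in disease incidence caused by moving the population BMI
#' distribution from `baseline` to `shifted`. Expectations are computed by
#' adaptive numeric integration (relative tolerance `rel.tol`), or in closed
#' form for point masses. A leftward mean shift with `rr_per_unit > 1` gives
#' a PIF in [0, 1).
#'
#' @param baseline,shifted [bmi_distribution()] objects.
#' @param rf A [risk_function()].
#' @param rel.tol Relative tolerance passed to [stats::integrate()].
#' @return A single number in (-Inf, 1].
#' @export
pif <- function(baseline, shifted, rf, rel.tol = 1e-8) {
  1 - dist_expect_rr(shifted, rf, rel.tol) / dist_expect_rr(baseline, rf, rel.tol)
}

#' Time-lag window between BMI change and disease incidence
#'
#' Disease incidence responds to the average BMI change over a past window:
#' 0--5 years for CVD, diabetes and osteoarthritis, 10--30 years for cancers.
#'
#' @param lower,upper Window bounds in years, `0 <= lower < upper`; both
#'   endpoints are included.
#' @export
lag_window <- function(lower, upper) {
  if (!(lower >= 0 && lower < upper)) {
    stop("lag window must satisfy 0 <= lower < upper")
  }
  structure(list(lower = as.integer(round(lower)),
                 upper = as.integer(round(upper))), class = "lag_window")
}

default_lag_windows <- function() {
  list(noncancer = lag_window(0, 5), cancer = lag_window(10, 30))
}

#' Lagged mean BMI change
#'
#' The BMI change driving incidence in simulation year `year` is the mean of
#' the per-year change series over years `[year - upper, year - lower]`
#' (inclusive). Years before the intervention, or beyond the recorded
#' history, count as zero, and the divisor is always the full window length
#' `upper - lower + 1`.
#'
#' @param history Numeric vector of per-year population-mean BMI changes;
#'   element 1 is the intervention year (simulation year 0).
#' @param year Simulation year (0 = intervention year).
#' @param window A [lag_window()].
#' @export
lagged_delta_bmi <- function(history, year, window) {
  if (!inherits(window, "lag_window")) stop("window must be a lag_window")
  yrs <- (year - window$upper):(year - window$lower)
  idx <- yrs + 1L
  vals <- ifelse(idx >= 1L & idx <= length(history), history[pmax(idx, 1L)], 0)
  sum(vals) / (window$upper - window$lower + 1L)
}

#' Post-intervention decay of the BMI effect
#'
#' @param rate BMI units regained per month after the intervention year
#'   (default 0.03).
#' @param enabled If `FALSE` the weight loss is permanent (no-decay
#'   scenario).
#' @export
decay_model <- function(rate = 0.03, enabled = TRUE) {
  if (rate < 0) stop("decay rate must be >= 0")
  structure(list(rate = rate, enabled = enabled), class = "decay_model")
}

#' Per-year BMI-change series under effect decay
#'
#' Year 1 (the intervention year) carries the full BMI change. From the
#' following January the lost BMI is regained linearly at `rate` units per
#' month until the change reaches zero, never overshooting; each later year's
#' value is the mean of its 12 monthly values. With decay disabled the series
#' is constant (permanent weight loss).
#'
#' @param initial_delta Initial BMI change, units; must be <= 0.
#' @param decay A [decay_model()].
#' @param horizon Series length in years, >= 1.
#' @return Numeric vector of length `horizon`.
#' @export
decay_profile <- function(initial_delta, decay = decay_model(), horizon) {
  if (initial_delta > 0) stop("initial_delta must be <= 0 (weight loss)")
  if (horizon < 1) stop("horizon must be >= 1")
  if (!decay$enabled || decay$rate == 0) {
    return(rep(initial_delta, horizon))
  }
  out <- numeric(horizon)
  out[1] <- initial_delta
  if (horizon > 1) {
    for (y in 2:horizon) {
      months <- 12L * (y - 2L) + 1:12
      out[y] <- mean(pmin(0, initial_delta + decay$rate * months))
    }
  }
  out
}

#' Months of nonzero effect after the intervention year
#'
#' @param initial_delta Initial BMI change (<= 0).
#' @param decay A [decay_model()].
#' @return Number of whole months after the intervention year with a nonzero
#'   BMI change (e.g. an initial change of -0.155 at 0.03 units/month is
#'   nonzero for 5 months and reaches zero during month 6).
#' @export
decay_duration_months <- function(initial_delta, decay = decay_model()) {
  if (!decay$enabled || decay$rate == 0) return(Inf)
  floor(abs(initial_delta) / decay$rate - 1e-12)
}
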