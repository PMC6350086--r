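#' Intervention uptake cascade
#'
#' The proportion of overweight/obese adults who receive the effective
#' intervention is the product of four stages: access to a smartphone,
#' exposure to the mass-media campaign, downloading a weight-loss app, and
#' regular use (10+ uses). Scenario analyses scale the download stage by a
#' multiplier (1, 1.5, 2), capped so the scaled proportion never exceeds 1.
#'
#' Central values: 74.42% smartphone access, 77.94% campaign exposure,
#' 13.46% download, 26% regular use.
#'
#' @param p_smartphone,p_exposed,p_download,p_regular_use Stage proportions
#'   in \[0, 1\].
#' @param download_multiplier Scenario factor applied to `p_download`.
#' @export
uptake_cascade <- function(p_smartphone = 0.7442, p_exposed = 0.7794,
                           p_download = 0.1346, p_regular_use = 0.26,
                           download_multiplier = 1) {
  p <- c(p_smartphone, p_exposed, p_download, p_regular_use)
  if (any(p < 0 | p > 1)) stop("cascade proportions must be in [0, 1]")
  if (download_multiplier < 0) stop("download_multiplier must be >= 0")
  structure(list(p_smartphone = p_smartphone, p_exposed = p_exposed,
                 p_download = p_download, p_regular_use = p_regular_use,
                 download_multiplier = download_multiplier),
            class = "uptake_cascade")
}

#' @param cascade An [uptake_cascade()].
#' @rdname uptake_cascade
#' @return `uptake_fraction()`: the product of the four stages (download
#'   stage capped at 1 after the multiplier), in \[0, 1\].
#' @export
uptake_fraction <- function(cascade) {
  cascade$p_smartphone * cascade$p_exposed *
    min(1, cascade$p_download * cascade$download_multiplier) *
    cascade$p_regular_use
}

#' Intervention effect size
#'
#' Additional weight loss for regular app users relative to control, from
#' meta-analysis of mobile-device weight-loss trials: -0.43 kg
#' (95% CI -0.61 to -0.25).
#'
#' @param delta_kg Weight change in kg (<= 0 in the base analysis).
#' @export
effect_size <- function(delta_kg = -0.43) {
  structure(list(delta_kg = delta_kg), class = "effect_size")
}

#' Convert a weight change to a BMI change
#'
#' @param delta_kg Weight change, kg.
#' @param height_m Height, metres (> 0).
#' @return BMI change, units kg/m^2.
#' @export
kg_to_bmi <- function(delta_kg, height_m) {
  if (any(height_m <= 0)) stop("height must be positive")
  delta_kg / height_m^2
}

#' Intervention cost components
#'
#' Web promotion on government health sites (NZ$72,000), one year of mass
#' media promotion (NZ$2,791,000) and identification of the top apps
#' (NZ$20,000); total NZ$2,883,000 (2011 NZ$).
#'
#' @param web_promotion,mass_media,app_identification Component costs, NZ$.
#' @export
cost_components <- function(web_promotion = 72000, mass_media = 2791000,
                            app_identification = 20000) {
  if (any(c(web_promotion, mass_media, app_identification) < 0)) {
    stop("cost components must be >= 0")
  }
  structure(list(web_promotion = web_promotion, mass_media = mass_media,
                 app_identification = app_identification),
            class = "cost_components")
}

#' @param cc A [cost_components()].
#' @rdname cost_components
#' @export
intervention_cost <- function(cc = cost_components()) {
  cc$web_promotion + cc$mass_media + cc$app_identification
}

#' Per-stratum BMI effect profile of the intervention
#'
#' For each stratum the population-mean BMI change per simulation year is
#' `uptake_fraction * overweight_prop * decay_profile(kg_to_bmi(delta_kg,
#' mean height))`: the effect operates only in the overweight/obese fraction
#' of each stratum and is spread over the whole stratum as a mean shift.
#' Strata younger than 18 at the intervention year get a zero profile (the
#' campaign targets adults); the downstream age-25 restriction on relative
#' risks is enforced by the life-table engine.
#'
#' @param ds A `baseline_dataset`.
#' @param cascade An [uptake_cascade()].
#' @param effect An [effect_size()].
#' @param decay A [decay_model()].
#' @param horizon Profile length in years.
#' @return A `bmi_effect_profile`: matrix `[stratum x year]` of mean BMI
#'   changes with the stratum grid as attribute.
#' @export
effect_profile <- function(ds, cascade = uptake_cascade(),
                           effect = effect_size(), decay = decay_model(),
                           horizon = MAX_AGE + 1L) {
  if (horizon < 1) stop("horizon must be >= 1")
  grid <- strata_grid()
  up <- uptake_fraction(cascade)
  hkey <- group_index(ds$heights$sex, ds$heights$ethnicity)
  hmean <- numeric(4L)
  hmean[hkey] <- ds$heights$mean
  ow <- numeric(nrow(grid))
  ogi <- group_index(ds$overweight$sex, ds$overweight$ethnicity)
  ow_m <- matrix(NA_real_, 4L, MAX_AGE + 1L)
  ow_m[cbind(ogi, ds$overweight$age + 1L)] <- ds$overweight$prop
  gi <- group_index(grid$sex, grid$ethnicity)
  ow <- ow_m[cbind(gi, grid$age0 + 1L)]

  profile <- matrix(0, nrow = nrow(grid), ncol = horizon)
  for (g in seq_len(4L)) {
    delta0 <- kg_to_bmi(effect$delta_kg, hmean[g])
    series <- decay_profile(delta0, decay, horizon)
    rows <- which(gi == g & grid$age0 >= 18L)
    if (length(rows) > 0) {
      profile[rows, ] <- (up * ow[rows]) %o% series
    }
  }
  structure(profile, class = "bmi_effect_profile", strata = grid,
            base_year = ds$base_year)
}

#' Population-weighted reach of the effective intervention
#'
#' The share of the whole adult (18+) population that ends up using a
#' weight-loss app regularly: the cascade product times each stratum's
#' overweight/obese proportion, weighted by population counts.
#'
#' @inheritParams effect_profile
#' @export
population_reach <- function(ds, cascade = uptake_cascade()) {
  up <- uptake_fraction(cascade)
  adults <- merge(ds$population, ds$overweight,
                  by = c("sex", "ethnicity", "age"))
  adults <- adults[adults$age >= 18L, ]
  up * sum(adults$count * adults$prop) / sum(adults$count)
}
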