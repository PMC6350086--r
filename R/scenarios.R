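#' Scenario definition
#'
#' @param download_multiplier Factor on the app-download stage (1 base case,
#'   1.5, 2 in scenarios).
#' @param discount_rate Annual discount rate (0.03 base case; 0 and 0.06 in
#'   scenarios).
#' @param decay If `FALSE`, weight loss is permanent (no-decay scenario).
#' @param equity If `TRUE`, non-Maori background mortality/morbidity is
#'   swapped onto Maori before the run (equity analysis).
#' @export
scenario <- function(download_multiplier = 1, discount_rate = 0.03,
                     decay = TRUE, equity = FALSE) {
  structure(list(download_multiplier = download_multiplier,
                 discount_rate = discount_rate, decay = decay,
                 equity = equity), class = "mslt_scenario")
}

#' Central (expected-value) model parameters
#'
#' One named list holding every model input the probabilistic sensitivity
#' analysis can perturb, at its central value: the uptake cascade, effect
#' size, decay rate, intervention cost, TMREL interpolation fraction, lag
#' window boundaries, and global multipliers/shifts on disease rates,
#' relative risks, morbidity, costs, trends and heights.
#'
#' @export
central_parameters <- function() {
  list(
    p_smartphone = 0.7442, p_exposed = 0.7794, p_download = 0.1346,
    p_regular_use = 0.26,
    effect_kg = -0.43,
    decay_rate = 0.03,
    intervention_cost = 2883000,
    tmrel_frac = 0,           # tmrel = 21 + 2 * frac
    lag_nc_upper = 5, lag_ca_lower = 10, lag_ca_upper = 30,
    rr_scale = 1,
    inc_mult = 1, cf_mult = 1, rem_mult = 1,
    pyld_mult = 1, dr_mult = 1,
    hs_cost_mult = 1,
    trend_shift = 0, trend_shift_diabetes = 0,
    height_shift = 0
  )
}

# Apply a parameter draw's global multipliers/shifts to a dataset copy.
perturb_dataset <- function(ds, par) {
  cp <- central_parameters()
  touched <- any(vapply(names(cp)[-(1:11)], function(nm) {
    !identical(par[[nm]], cp[[nm]])
  }, logical(1)))
  if (!touched) return(ds)
  ds$pyld <- data.table::copy(ds$pyld)
  ds$pyld$pyld_rate <- pmin(1, ds$pyld$pyld_rate * par$pyld_mult)
  ds$base_costs <- data.table::copy(ds$base_costs)
  ds$base_costs$cost <- ds$base_costs$cost * par$hs_cost_mult
  ds$heights <- data.table::copy(ds$heights)
  ds$heights$mean <- ds$heights$mean + par$height_shift
  ds$diseases <- lapply(stats::setNames(names(ds$diseases), names(ds$diseases)),
                        function(dn) {
    d <- data.table::copy(ds$diseases[[dn]])
    d$incidence <- pmin(1, d$incidence * par$inc_mult)
    d$case_fatality <- pmin(1, d$case_fatality * par$cf_mult)
    d$remission <- pmin(1, d$remission * par$rem_mult)
    d$dr <- pmax(0, d$dr * par$dr_mult)
    d$rr_per_unit <- pmax(1, exp(log(d$rr_per_unit) * par$rr_scale))
    d$cost_first_year <- d$cost_first_year * par$hs_cost_mult
    d$cost_prevalent <- d$cost_prevalent * par$hs_cost_mult
    d$cost_last6m <- d$cost_last6m * par$hs_cost_mult
    shift <- if (dn == "diabetes") par$trend_shift_diabetes else par$trend_shift
    d$trend_inc <- d$trend_inc + shift
    d$trend_cf <- d$trend_cf + shift
    d
  })
  ds
}

# lag windows from a parameter draw, rounded to whole years and kept valid
draw_lag_windows <- function(par) {
  nc_up <- max(1L, as.integer(round(par$lag_nc_upper)))
  ca_lo <- max(1L, as.integer(round(par$lag_ca_lower)))
  ca_up <- max(ca_lo + 1L, as.integer(round(par$lag_ca_upper)))
  list(noncancer = lag_window(0, nc_up), cancer = lag_window(ca_lo, ca_up))
}

#' Run one scenario at a given parameter set
#'
#' Wires the full pipeline: (optional) equity swap, parameter perturbations,
#' uptake cascade and BMI effect profile, the multistate life table, and the
#' discounted summary.
#'
#' @param ds A `baseline_dataset`.
#' @param scen A [scenario()].
#' @param par Parameter list as from [central_parameters()] (a PSA draw
#'   overrides entries).
#' @param keep_run Attach the raw `mslt_run` to the result.
#' @return A `scenario_result` (see [summarize_run()]).
#' @export
run_scenario <- function(ds, scen = scenario(), par = central_parameters(),
                         keep_run = FALSE) {
  if (isTRUE(scen$equity)) ds <- equity_swap(ds)
  ds <- perturb_dataset(ds, par)
  cascade <- uptake_cascade(par$p_smartphone, par$p_exposed, par$p_download,
                            par$p_regular_use,
                            download_multiplier = scen$download_multiplier)
  eff <- effect_size(min(0, par$effect_kg))
  decay <- decay_model(par$decay_rate, enabled = isTRUE(scen$decay))
  profile <- effect_profile(ds, cascade, eff, decay)
  run <- run_mslt(ds, profile, tmrel = 21 + 2 * par$tmrel_frac,
                  lag_windows = draw_lag_windows(par))
  res <- summarize_run(run, ds, discount_rate = scen$discount_rate,
                       intervention_cost_nzd = par$intervention_cost)
  if (keep_run) res$run <- run
  res
}

#' Run the paper-style scenario grid
#'
#' Base case plus download multipliers 1.5 and 2, discount rates 0% and 6%,
#' the no-decay (permanent weight loss) scenario and the equity swap, all at
#' central parameter values.
#'
#' @param ds A `baseline_dataset`.
#' @param par Central parameter list.
#' @return A `data.table` with one row per scenario: QALYs gained, net cost,
#'   ICER (NZ$ and US$) and Maori/non-Maori breakdowns.
#' @export
run_scenario_grid <- function(ds, par = central_parameters()) {
  scens <- list(
    base = scenario(),
    download_x1_5 = scenario(download_multiplier = 1.5),
    download_x2 = scenario(download_multiplier = 2),
    discount_0 = scenario(discount_rate = 0),
    discount_6 = scenario(discount_rate = 0.06),
    no_decay = scenario(decay = FALSE),
    equity = scenario(equity = TRUE)
  )
  data.table::rbindlist(lapply(names(scens), function(nm) {
    r <- run_scenario(ds, scens[[nm]], par)
    data.table(scenario = nm,
               download_multiplier = scens[[nm]]$download_multiplier,
               discount_rate = scens[[nm]]$discount_rate,
               decay = scens[[nm]]$decay, equity = scens[[nm]]$equity,
               qalys = r$delta_qalys,
               qalys_maori = r$by_ethnicity$maori$qalys,
               qalys_non_maori = r$by_ethnicity$non_maori$qalys,
               net_cost_nzd = r$net_cost_nzd,
               icer_nzd = r$icer_nzd, icer_usd = r$icer_usd,
               dominant = r$dominant)
  }))
}
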