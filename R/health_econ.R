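PPP_NZD_PER_USD <- 1.486
CE_THRESHOLD_NZD <- 45000

#' Discount a per-year stream to the base year
#'
#' Year-end convention: a value accruing in calendar year `t` is divided by
#' `(1 + rate)^(t - 2011)`.
#'
#' @param stream Numeric vector (or `[stratum x year]` matrix) of per-year
#'   values.
#' @param rate Annual discount rate (>= 0); 3% in the base case, 0% and 6%
#'   in scenario analyses.
#' @param years Calendar years of the stream columns/elements.
#' @param base_year Discounting anchor year.
#' @return The discounted total (scalar for a vector; per-stratum vector for
#'   a matrix).
#' @export
discount <- function(stream, rate = 0.03, years = NULL, base_year = BASE_YEAR) {
  if (rate < 0) stop("discount rate must be >= 0")
  if (is.matrix(stream)) {
    if (is.null(years)) years <- base_year + seq_len(ncol(stream)) - 1L
    as.vector(stream %*% (1 / (1 + rate)^(years - base_year)))
  } else {
    if (is.null(years)) years <- base_year + seq_along(stream) - 1L
    sum(stream / (1 + rate)^(years - base_year))
  }
}

#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost Incremental net cost, NZ$.
#' @param delta_qalys Incremental QALYs (must be nonzero).
#' @return List with `icer` (NZ$ per QALY) and `dominant` (`TRUE` when the
#'   intervention saves money and gains health, i.e. the "cost-saving,
#'   health-gaining" quadrant).
#' @export
icer <- function(delta_cost, delta_qalys) {
  if (delta_qalys == 0) stop("ICER undefined: delta_qalys is zero")
  list(icer = delta_cost / delta_qalys,
       dominant = delta_cost < 0 && delta_qalys > 0)
}

#' Convert NZ$ to US$ at purchasing power parity
#'
#' @param nzd Amount in NZ$ (2011).
#' @param ppp NZ$ per US$ (OECD PPP 2011: 1.486).
#' @param signif Optional number of significant digits for reporting.
#' @export
to_usd <- function(nzd, ppp = PPP_NZD_PER_USD, signif = NULL) {
  if (ppp <= 0) stop("ppp must be positive")
  usd <- nzd / ppp
  if (!is.null(signif)) usd <- base::signif(usd, signif)
  usd
}

#' Undiscounted cost ledger of a model run
#'
#' @param run An `mslt_run`.
#' @return A `data.table` with per-stratum, per-year, per-arm undiscounted
#'   health-system costs (NZ$ per member of the 2011 stratum cohort).
#' @export
accrue_costs <- function(run) {
  grid <- run$strata
  T <- length(run$years)
  data.table::rbindlist(lapply(c("bau", "int"), function(arm) {
    m <- run[[paste0("cost_", arm)]]
    data.table(sex = rep(grid$sex, T), ethnicity = rep(grid$ethnicity, T),
               age0 = rep(grid$age0, T), year = rep(run$years, each = nrow(grid)),
               arm = arm, cost = as.vector(m))
  }))
}

per_stratum_deltas <- function(run, rate) {
  list(qaly = discount(run$qaly_int - run$qaly_bau, rate, run$years),
       cost = discount(run$cost_int - run$cost_bau, rate, run$years))
}

age_standardized_rate <- function(per1000, pop, age0, std) {
  band <- findInterval(age0, std$age_lo)
  num <- 0
  for (b in seq_len(nrow(std))) {
    rows <- which(band == b)
    if (length(rows) == 0 || sum(pop[rows]) == 0) next
    num <- num + std$weight[b] * sum(per1000[rows] * pop[rows]) / sum(pop[rows])
  }
  num
}

#' Summarise a model run into scenario results
#'
#' Aggregates per-stratum discounted QALY and cost differences (scaled by
#' stratum population counts) into the reporting layout: totals and
#' per-1000-adult rates by ethnicity and sex, age-standardized per-capita
#' rates (direct standardization to the dataset's standard population),
#' per-capita rates restricted to the overweight/obese, net cost (cost
#' offsets plus the intervention cost) and the ICER in NZ$ and US$. Results
#' are restricted to cohorts aged `scope_age` and over in the base year.
#'
#' @param run An `mslt_run`.
#' @param ds The `baseline_dataset` the run used.
#' @param discount_rate Annual discount rate.
#' @param intervention_cost_nzd One-off intervention cost added to the cost
#'   difference.
#' @param scope_age Youngest base-year age included in reporting.
#' @return A `scenario_result` list.
#' @export
summarize_run <- function(run, ds, discount_rate = 0.03,
                          intervention_cost_nzd = intervention_cost(),
                          scope_age = 25L) {
  grid <- run$strata
  keep <- grid$age0 >= scope_age
  if (!any(keep)) stop("empty reporting scope")
  d <- per_stratum_deltas(run, discount_rate)
  pop <- numeric(nrow(grid))
  pkey <- paste(ds$population$sex, ds$population$ethnicity, ds$population$age)
  pop <- ds$population$count[match(paste(grid$sex, grid$ethnicity, grid$age0), pkey)]
  owkey <- paste(ds$overweight$sex, ds$overweight$ethnicity, ds$overweight$age)
  owp <- ds$overweight$prop[match(paste(grid$sex, grid$ethnicity, grid$age0), owkey)]

  dq <- d$qaly * pop
  dc <- d$cost * pop
  total_q <- sum(dq[keep])
  total_cost_offsets <- sum(dc[keep])
  net_cost <- intervention_cost_nzd + total_cost_offsets

  by_group <- function(rows) {
    list(qalys = sum(dq[rows & keep]),
         cost = sum(dc[rows & keep]),
         per_1000 = 1000 * sum(dq[rows & keep]) / sum(pop[rows & keep]),
         per_1000_overweight = 1000 * sum(dq[rows & keep]) /
           sum((pop * owp)[rows & keep]),
         age_standardized_per_1000 = age_standardized_rate(
           1000 * ifelse(pop > 0, dq / pop, 0)[rows & keep],
           pop[rows & keep], grid$age0[rows & keep], ds$standard_population))
  }

  res <- list(
    discount_rate = discount_rate,
    intervention_cost_nzd = intervention_cost_nzd,
    delta_qalys = total_q,
    cost_offsets_nzd = total_cost_offsets,
    net_cost_nzd = net_cost,
    net_cost_usd = to_usd(net_cost),
    per_stratum = data.table(grid, population = pop, delta_qalys = dq,
                             delta_cost = dc, in_scope = keep),
    by_ethnicity = lapply(
      stats::setNames(ETHNICITIES, ETHNICITIES),
      function(e) by_group(grid$ethnicity == e)),
    by_sex = lapply(stats::setNames(SEXES, SEXES),
                    function(s) by_group(grid$sex == s)),
    combined = by_group(rep(TRUE, nrow(grid)))
  )
  if (total_q != 0) {
    ic <- icer(net_cost, total_q)
    res$icer_nzd <- ic$icer
    res$icer_usd <- to_usd(ic$icer)
    res$dominant <- ic$dominant
  } else {
    res$icer_nzd <- NA_real_
    res$icer_usd <- NA_real_
    res$dominant <- FALSE
  }
  structure(res, class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> discount", sprintf("%.0f%%", 100 * x$discount_rate), "\n")
  cat(sprintf("  QALYs gained: %.3g (Maori %.3g / non-Maori %.3g)\n",
              x$delta_qalys, x$by_ethnicity$maori$qalys,
              x$by_ethnicity$non_maori$qalys))
  cat(sprintf("  net cost: NZ$%.4g (US$%.4g)\n", x$net_cost_nzd, x$net_cost_usd))
  if (is.finite(x$icer_nzd)) {
    if (isTRUE(x$dominant)) cat("  cost-saving, health-gaining (dominant)\n")
    else cat(sprintf("  ICER: NZ$%.4g / US$%.4g per QALY\n",
                     x$icer_nzd, x$icer_usd))
  }
  invisible(x)
}
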