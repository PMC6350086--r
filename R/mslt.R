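#' Disease rate trends
#'
#' Annual proportional trends apply from the base year until 2026 and are
#' then frozen: `rate(year) = rate(2011) * (1 + trend)^(min(year, 2026) -
#' 2011)`.
#'
#' @param trend Annual proportional change.
#' @param year Calendar year (>= 2011).
#' @export
trend_factor <- function(trend, year) {
  if (any(year < BASE_YEAR)) stop("year must be >= ", BASE_YEAR)
  (1 + trend)^(pmin(year, TREND_HORIZON) - BASE_YEAR)
}

#' @param spec A disease rate table (one element of `ds$diseases`).
#' @rdname trend_factor
#' @return `apply_trends()`: the table with `incidence`, `case_fatality` and
#'   `remission` scaled to `year`.
#' @export
apply_trends <- function(spec, year) {
  out <- data.table::copy(data.table::as.data.table(spec))
  out$incidence <- pmin(1, out$incidence * trend_factor(out$trend_inc, year))
  out$case_fatality <- pmin(1, out$case_fatality * trend_factor(out$trend_cf, year))
  out$remission <- pmin(1, out$remission * trend_factor(out$trend_rem, year))
  out[]
}

#' One annual cycle of a disease life table
#'
#' The disease life table is a closed three-state system (healthy, prevalent,
#' dead-of-disease). Each year, `healthy * incidence * (1 - pif)` flow in,
#' `prevalent * remission` flow back to healthy and `prevalent *
#' case_fatality` die of the disease; the three states always sum to 1.
#'
#' @param state List with numeric vectors `healthy`, `prevalent`, `dead`.
#' @param rates List with `incidence`, `case_fatality`, `remission`.
#' @param pif Population impact fraction(s) scaling down the inflow (<= 1).
#' @param label Disease name used in error messages.
#' @return The next-year state, plus flows `new_cases`, `remissions`,
#'   `deaths`.
#' @export
step_disease <- function(state, rates, pif = 0, label = "disease") {
  if (any(pif > 1)) stop("pif must be <= 1")
  inc <- rates$incidence * (1 - pif)
  new_cases <- state$healthy * inc
  remissions <- state$prevalent * rates$remission
  deaths <- state$prevalent * rates$case_fatality
  healthy <- state$healthy - new_cases + remissions
  prevalent <- state$prevalent + new_cases - remissions - deaths
  dead <- state$dead + deaths
  bad <- which(healthy < -1e-12 | healthy > 1 + 1e-12 |
               prevalent < -1e-12 | prevalent > 1 + 1e-12 |
               dead < -1e-12 | dead > 1 + 1e-12)
  if (length(bad) > 0) {
    stop("incoherent rates for ", label, ": state proportion outside [0,1] ",
         "at stratum index ", bad[1])
  }
  list(healthy = healthy, prevalent = prevalent, dead = dead,
       new_cases = new_cases, remissions = remissions, deaths = deaths)
}

#' Swap non-Maori background rates onto Maori strata (equity analysis)
#'
#' Returns a dataset in which Maori all-cause mortality and morbidity (pYLD)
#' are replaced by the same-sex, same-age non-Maori values, leaving all other
#' inputs unchanged. Used to ask what the intervention would deliver for
#' Maori absent their higher background burden; idempotent.
#'
#' @param ds A `baseline_dataset`.
#' @export
equity_swap <- function(ds) {
  for (comp in c("mortality", "pyld")) {
    dt <- data.table::copy(ds[[comp]])
    vcol <- setdiff(names(dt), c("sex", "ethnicity", "age"))
    nm <- dt[dt$ethnicity == "non_maori", ]
    key <- paste(dt$sex, dt$age)
    nmkey <- paste(nm$sex, nm$age)
    repl <- nm[[vcol]][match(key, nmkey)]
    dt[[vcol]] <- ifelse(dt$ethnicity == "maori", repl, dt[[vcol]])
    ds[[comp]] <- dt
  }
  ds
}

# ---- engine internals -------------------------------------------------------

QUAD_NODES <- 24L  # relative error ~1e-11 against adaptive integration

# Gauss-Legendre nodes/weights on [0, 1]
gl_rule <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pracma::gaussLegendre(QUAD_NODES, 0, 1)
    cache
  }
})

# log-normal parameters per sex-ethnicity group and BMI age band, plus the
# band lookup by age; rows keyed (band - 1) * 4 + group
build_bmi_nodes <- function(ds) {
  bands <- unique(ds$bmi[, c("age_lo", "age_hi")])
  data.table::setkeyv(bands, "age_lo")
  nb <- nrow(bands)
  meanlog <- sdlog <- rep(NA_real_, 4L * nb)
  gi <- group_index(ds$bmi$sex, ds$bmi$ethnicity)
  bi <- match(ds$bmi$age_lo, bands$age_lo)
  lp <- lnorm_params(ds$bmi$mean, ds$bmi$sd)
  key <- (bi - 1L) * 4L + gi
  meanlog[key] <- lp$meanlog
  sdlog[key] <- lp$sdlog
  band_of_age <- findInterval(0:MAX_AGE, bands$age_lo)
  list(meanlog = meanlog, sdlog = sdlog, band_of_age = band_of_age)
}

# E[RR(X + delta)] for X log-normal: exact tail masses (below the TMREL and
# above the risk cap) plus Gauss-Legendre on the smooth middle segment; the
# integrand is analytic there, so 40 nodes are accurate to machine level
expect_rr_lnorm <- function(meanlog, sdlog, lr, delta, tmrel, cap = BMI_CAP) {
  gl <- gl_rule()
  a <- tmrel - delta          # exposure enters the sloped region above a
  b <- cap - delta
  width <- cap - tmrel
  X <- outer(rep(1, length(meanlog)), gl$x * width) + a
  dens <- dlnorm(X, meanlog, sdlog)
  integ <- as.vector((dens * exp(lr * (X + delta - tmrel))) %*% gl$w) * width
  plnorm(a, meanlog, sdlog) + integ +
    exp(lr * width) * plnorm(b, meanlog, sdlog, lower.tail = FALSE)
}

disease_matrices <- function(d) {
  list(inc = group_age_matrix(d, "incidence"),
       cf = group_age_matrix(d, "case_fatality"),
       rem = group_age_matrix(d, "remission"),
       dr = group_age_matrix(d, "dr"),
       rr = group_age_matrix(d, "rr_per_unit"),
       cost_first_year = d$cost_first_year[1],
       cost_prevalent = d$cost_prevalent[1],
       cost_last6m = d$cost_last6m[1],
       trend_inc = d$trend_inc[1], trend_cf = d$trend_cf[1],
       trend_rem = d$trend_rem[1])
}

# lagged-mean matrix: column t holds the window mean of the profile at
# simulation year t-1 for every stratum
lag_matrix <- function(profile, window, T) {
  S <- nrow(profile)
  P <- matrix(0, S, T)
  n <- min(ncol(profile), T)
  P[, seq_len(n)] <- profile[, seq_len(n)]
  cs <- cbind(0, t(apply(P, 1L, cumsum)))
  out <- matrix(0, S, T)
  len <- window$upper - window$lower + 1L
  for (t in seq_len(T)) {
    tau <- t - 1L
    lo <- max(1L, tau - window$upper + 1L)
    hi <- min(T, tau - window$lower + 1L)
    if (hi >= lo) out[, t] <- (cs[, hi + 1L] - cs[, lo]) / len
  }
  out
}

BMI_CAP <- 60  # exposure cap of risk_function(), keeping E[RR] finite

# PIF matrix [stratum x year] for one disease via Gauss-Hermite quadrature;
# zero where the lagged BMI change is zero or attained age < 25
pif_matrix <- function(dl, dm, nodes, tmrel, amat, gi, min_age = 25L) {
  S <- nrow(dl); T <- ncol(dl)
  out <- matrix(0, S, T)
  nzcols <- which(colSums(abs(dl)) > 0)
  if (length(nzcols) == 0) return(out)

  ## gather every nonzero (stratum, year) cell into one batch
  cells <- lapply(nzcols, function(t) {
    age <- amat[, t]
    rows <- which(dl[, t] != 0 & age >= min_age)
    if (length(rows) == 0) return(NULL)
    cbind(row = rows, t = t, age = age[rows])
  })
  cells <- do.call(rbind, cells)
  if (is.null(cells) || nrow(cells) == 0) return(out)

  rowkey <- (nodes$band_of_age[cells[, "age"] + 1L] - 1L) * 4L + gi[cells[, "row"]]
  ml <- nodes$meanlog[rowkey]; sl <- nodes$sdlog[rowkey]
  lr <- log(dm$rr[cbind(gi[cells[, "row"]], cells[, "age"] + 1L)])
  delta <- dl[cells[, c("row", "t")]]

  ## the zero-shift expectation depends only on (band, group, rr): compute
  ## once per unique key and map back
  key <- rowkey + 1e5 * lr
  uk <- !duplicated(key)
  e_base_u <- expect_rr_lnorm(ml[uk], sl[uk], lr[uk], 0, tmrel)
  e_base <- e_base_u[match(key, key[uk])]
  e_shift <- expect_rr_lnorm(ml, sl, lr, delta, tmrel)
  out[cells[, c("row", "t")]] <- 1 - e_shift / e_base
  out
}

#' Run the multistate life table under BAU and intervention
#'
#' Evolves the main cohort life table and one life table per disease from the
#' base year (2011) to cohort extinction (maximum age 110), in annual cycles,
#' for the business-as-usual arm and an intervention arm whose disease inflow
#' is reduced by per-year population impact fractions derived from the lagged
#' BMI effect profile. Life-years credit deaths half a cycle (midpoint rule);
#' QALYs down-weight life-years by prevalent YLD adjusted for the morbidity
#' averted (disability rate times the prevalence difference against BAU); the
#' intervention arm's mortality is relieved by the case-fatality-weighted
#' prevalence difference. Health-system costs are accrued per person-year:
#' the baseline cost applies to the alive fraction without BMI-related
#' disease, plus first-year, prevalent and last-6-months disease costs.
#'
#' With a zero (or `NULL`) effect profile the two arms are bitwise
#' identical.
#'
#' @param ds A `baseline_dataset`.
#' @param profile A `bmi_effect_profile` from [effect_profile()], or `NULL`
#'   for a null intervention.
#' @param tmrel TMREL in BMI units (relative risk is 1 below it).
#' @param lag_windows List with [lag_window()]s `noncancer` and `cancer`.
#' @param min_rr_age Youngest attained age at which relative risks (hence
#'   PIFs) apply.
#' @param keep_disease_tables Store the full per-disease state trajectories
#'   (memory-heavy; used by structural tests).
#' @return An `mslt_run` with `[stratum x year]` matrices of life-years,
#'   QALYs and costs for both arms, alive trajectories, and the stratum grid.
#' @export
run_mslt <- function(ds, profile = NULL, tmrel = 21,
                     lag_windows = default_lag_windows(), min_rr_age = 25L,
                     keep_disease_tables = FALSE) {
  T <- MAX_AGE + 1L
  grid <- strata_grid()
  S <- nrow(grid)
  gi <- group_index(grid$sex, grid$ethnicity)
  si <- match(grid$sex, SEXES)
  amat <- vapply(seq_len(T), function(t) pmin(grid$age0 + t - 1L, MAX_AGE),
                 integer(S))

  acm_m <- group_age_matrix(ds$mortality, "acm_rate")
  pyld_m <- group_age_matrix(ds$pyld, "pyld_rate")
  bc <- matrix(NA_real_, 2L, MAX_AGE + 1L)
  bc[cbind(match(ds$base_costs$sex, SEXES), ds$base_costs$age + 1L)] <-
    ds$base_costs$cost
  dms <- lapply(ds$diseases, disease_matrices)

  if (is.null(profile)) profile <- matrix(0, S, T)
  nodes <- build_bmi_nodes(ds)
  dl <- list(noncancer = lag_matrix(profile, lag_windows$noncancer, T),
             cancer = lag_matrix(profile, lag_windows$cancer, T))
  pifs <- lapply(names(dms), function(dn) {
    pif_matrix(dl[[disease_group(dn)]], dms[[dn]], nodes, tmrel, amat, gi,
               min_age = min_rr_age)
  })
  names(pifs) <- names(dms)

  ## initial states: steady-state prevalence at the 2011 attained age
  st <- lapply(names(dms), function(dn) {
    dm <- dms[[dn]]
    idx <- cbind(gi, grid$age0 + 1L)
    p0 <- steady_prevalence(dm$inc[idx], dm$cf[idx], dm$rem[idx])
    list(bau = list(healthy = 1 - p0, prevalent = p0, dead = rep(0, S)),
         int = list(healthy = 1 - p0, prevalent = p0, dead = rep(0, S)))
  })
  names(st) <- names(dms)

  alive_bau <- matrix(0, S, T + 1L); alive_bau[, 1] <- 1
  alive_int <- alive_bau
  ly_bau <- ly_int <- qaly_bau <- qaly_int <- cost_bau <- cost_int <-
    matrix(0, S, T)
  tables <- if (keep_disease_tables) {
    lapply(st, function(x) list(
      bau = list(healthy = matrix(0, S, T + 1L), prevalent = matrix(0, S, T + 1L),
                 dead = matrix(0, S, T + 1L)),
      int = list(healthy = matrix(0, S, T + 1L), prevalent = matrix(0, S, T + 1L),
                 dead = matrix(0, S, T + 1L))))
  } else NULL
  if (keep_disease_tables) {
    for (dn in names(st)) for (arm in c("bau", "int")) {
      tables[[dn]][[arm]]$healthy[, 1] <- st[[dn]][[arm]]$healthy
      tables[[dn]][[arm]]$prevalent[, 1] <- st[[dn]][[arm]]$prevalent
      tables[[dn]][[arm]]$dead[, 1] <- st[[dn]][[arm]]$dead
    }
  }

  ## hoist per-disease per-year trend factors; clamping inside the year loop
  ## is only needed where a rate could actually leave [0, 1]
  years_all <- BASE_YEAR + 0:(T - 1L)
  tf <- lapply(dms, function(dm) list(
    inc = trend_factor(dm$trend_inc, years_all),
    cf = trend_factor(dm$trend_cf, years_all),
    rem = trend_factor(dm$trend_rem, years_all)))
  needs_clamp <- vapply(names(dms), function(dn) {
    dm <- dms[[dn]]
    max(dm$inc) * max(tf[[dn]]$inc) > 1 ||
      max(dm$cf) * max(tf[[dn]]$cf) + max(dm$rem) * max(tf[[dn]]$rem) > 1
  }, logical(1))

  for (t in seq_len(T)) {
    year <- BASE_YEAR + t - 1L
    idx <- cbind(gi, amat[, t] + 1L)
    relief_mort <- numeric(S)
    relief_morb <- numeric(S)
    prevsum_bau <- numeric(S); prevsum_int <- numeric(S)
    dcost_bau <- numeric(S); dcost_int <- numeric(S)

    for (dn in names(dms)) {
      dm <- dms[[dn]]
      i_ <- dm$inc[idx] * tf[[dn]]$inc[t]
      f_ <- dm$cf[idx] * tf[[dn]]$cf[t]
      r_ <- dm$rem[idx] * tf[[dn]]$rem[t]
      if (needs_clamp[[dn]]) {
        i_ <- pmin(1, i_); f_ <- pmin(1, f_); r_ <- pmin(1, r_)
        tot_exit <- f_ + r_
        over <- tot_exit > 1
        if (any(over)) {
          f_[over] <- f_[over] / tot_exit[over]
          r_[over] <- r_[over] / tot_exit[over]
        }
      }
      s_b <- st[[dn]]$bau; s_i <- st[[dn]]$int
      dprev <- s_b$prevalent - s_i$prevalent
      relief_mort <- relief_mort + f_ * dprev
      relief_morb <- relief_morb + dm$dr[idx] * dprev
      prevsum_bau <- prevsum_bau + s_b$prevalent
      prevsum_int <- prevsum_int + s_i$prevalent

      ## lean inline stepping (the exported step_disease adds bound checks)
      new_b <- s_b$healthy * i_
      rem_b <- s_b$prevalent * r_
      dth_b <- s_b$prevalent * f_
      p_b <- s_b$prevalent + new_b - rem_b - dth_b
      st[[dn]]$bau <- list(healthy = s_b$healthy - new_b + rem_b,
                           prevalent = p_b, dead = s_b$dead + dth_b)
      new_i <- s_i$healthy * (i_ * (1 - pifs[[dn]][, t]))
      rem_i <- s_i$prevalent * r_
      dth_i <- s_i$prevalent * f_
      p_i <- s_i$prevalent + new_i - rem_i - dth_i
      st[[dn]]$int <- list(healthy = s_i$healthy - new_i + rem_i,
                           prevalent = p_i, dead = s_i$dead + dth_i)

      dcost_bau <- dcost_bau + dm$cost_first_year * new_b +
        dm$cost_prevalent * (p_b - new_b) + dm$cost_last6m * dth_b
      dcost_int <- dcost_int + dm$cost_first_year * new_i +
        dm$cost_prevalent * (p_i - new_i) + dm$cost_last6m * dth_i
      if (keep_disease_tables) {
        for (arm in c("bau", "int")) {
          s <- st[[dn]][[arm]]
          tables[[dn]][[arm]]$healthy[, t + 1L] <- s$healthy
          tables[[dn]][[arm]]$prevalent[, t + 1L] <- s$prevalent
          tables[[dn]][[arm]]$dead[, t + 1L] <- s$dead
        }
      }
    }

    m_bau <- acm_m[idx]
    m_int <- m_bau - relief_mort
    # relief may be slightly negative later in life (survivors age into
    # disease); a cohort at the terminal age then overshoots 1 by a hair.
    # Only gross violations signal incoherent rates.
    if (any(m_int < -1e-6 | m_int > 1.01)) {
      stop("adjusted mortality outside [0,1] in year ", year)
    }
    m_int <- pmin(pmax(m_int, 0), 1)
    a_b0 <- alive_bau[, t]; a_i0 <- alive_int[, t]
    a_b1 <- a_b0 * (1 - m_bau); a_i1 <- a_i0 * (1 - m_int)
    alive_bau[, t + 1L] <- a_b1; alive_int[, t + 1L] <- a_i1
    ly_b <- (a_b0 + a_b1) / 2; ly_i <- (a_i0 + a_i1) / 2
    ly_bau[, t] <- ly_b; ly_int[, t] <- ly_i

    pyld <- pyld_m[idx]
    qaly_bau[, t] <- ly_b * pmin(pmax(1 - pyld, 0), 1)
    qaly_int[, t] <- ly_i * pmin(pmax(1 - (pyld - relief_morb), 0), 1)

    base_c <- bc[cbind(si, amat[, t] + 1L)]
    cost_bau[, t] <- base_c * ly_b * pmax(0, 1 - prevsum_bau) + ly_b * dcost_bau
    cost_int[, t] <- base_c * ly_i * pmax(0, 1 - prevsum_int) + ly_i * dcost_int
  }

  structure(list(
    strata = grid, years = BASE_YEAR + 0:(T - 1L),
    alive_bau = alive_bau, alive_int = alive_int,
    ly_bau = ly_bau, ly_int = ly_int,
    qaly_bau = qaly_bau, qaly_int = qaly_int,
    cost_bau = cost_bau, cost_int = cost_int,
    disease_tables = tables, pifs = pifs
  ), class = "mslt_run")
}

#' @export
print.mslt_run <- function(x, ...) {
  cat("<mslt_run>", length(x$years), "years x", nrow(x$strata), "strata\n")
  dq <- sum(x$qaly_int - x$qaly_bau)
  cat(sprintf("  undiscounted per-capita QALY difference (sum over strata): %.6g\n", dq))
  invisible(x)
}
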