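#' Load the packaged intervention configuration
#'
#' The central uptake-cascade proportions, effect size, decay rate and cost
#' components ship as `inst/extdata/intervention.yaml`.
#'
#' @param path YAML file path.
#' @export
read_intervention_config <- function(path = system.file("extdata", "intervention.yaml",
                                                        package = "appmslt")) {
  yaml::read_yaml(path)
}

#' Load a scenario grid from YAML
#'
#' @param path YAML file path; the packaged default mirrors the reported
#'   scenario grid (download multipliers, discount rates, no-decay, equity).
#' @export
read_scenarios <- function(path = system.file("extdata", "scenarios.yaml",
                                              package = "appmslt")) {
  raw <- yaml::read_yaml(path)
  lapply(raw$scenarios, function(s) {
    sc <- scenario(download_multiplier = s$download_multiplier,
                   discount_rate = s$discount_rate,
                   decay = isTRUE(s$decay), equity = isTRUE(s$equity))
    attr(sc, "name") <- s$name
    sc
  })
}

round_meaningful <- function(x, digits = 3) signif(x, digits)

#' Paper-style results table for one scenario
#'
#' Rows per subpopulation (Maori, non-Maori, combined; all/men/women;
#' per-capita and per-capita-overweight), columns for QALYs gained, net
#' cost, and the ICER in NZ$ and US$; totals rounded to 3 meaningful digits
#' at the report layer only.
#'
#' @param res A `scenario_result`.
#' @param label Scenario label for the first column.
#' @export
results_table <- function(res, label = "base") {
  eth <- res$by_ethnicity
  rows <- list(
    list(subgroup = "all", non_maori = eth$non_maori$qalys,
         maori = eth$maori$qalys, combined = res$delta_qalys),
    list(subgroup = "men", non_maori = NA_real_, maori = NA_real_,
         combined = res$by_sex$male$qalys),
    list(subgroup = "women", non_maori = NA_real_, maori = NA_real_,
         combined = res$by_sex$female$qalys),
    list(subgroup = "per_capita_per_1000",
         non_maori = eth$non_maori$per_1000, maori = eth$maori$per_1000,
         combined = res$combined$per_1000),
    list(subgroup = "per_capita_age_standardized",
         non_maori = eth$non_maori$age_standardized_per_1000,
         maori = eth$maori$age_standardized_per_1000,
         combined = res$combined$age_standardized_per_1000),
    list(subgroup = "per_capita_overweight_per_1000",
         non_maori = eth$non_maori$per_1000_overweight,
         maori = eth$maori$per_1000_overweight,
         combined = res$combined$per_1000_overweight)
  )
  dt <- data.table::rbindlist(rows)
  dt[, c("scenario", "net_cost_nzd", "icer_nzd", "icer_usd") :=
       list(label, round_meaningful(res$net_cost_nzd),
            round_meaningful(res$icer_nzd), round_meaningful(res$icer_usd))]
  num <- setdiff(names(dt), c("scenario", "subgroup"))
  for (cl in num) dt[[cl]] <- round_meaningful(dt[[cl]])
  data.table::setcolorder(dt, c("scenario", "subgroup"))
  dt[]
}

#' Write scenario-grid results to CSV and JSON
#'
#' @param grid Output of [run_scenario_grid()].
#' @param out_dir Output directory (created if needed).
#' @export
write_results <- function(grid, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(grid, file.path(out_dir, "results.csv"), row.names = FALSE)
  jsonlite::write_json(grid, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}
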