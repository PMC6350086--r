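DATASET_SCHEMAS <- list(
  population = c("sex", "ethnicity", "age", "count"),
  mortality = c("sex", "ethnicity", "age", "acm_rate"),
  pyld = c("sex", "ethnicity", "age", "pyld_rate"),
  base_costs = c("sex", "age", "cost"),
  bmi = c("sex", "ethnicity", "age_lo", "age_hi", "mean", "sd"),
  heights = c("sex", "ethnicity", "mean", "sd"),
  overweight = c("sex", "ethnicity", "age", "prop"),
  standard_population = c("age_lo", "age_hi", "weight")
)
DISEASE_SCHEMA <- c("age", "sex", "ethnicity", "incidence", "case_fatality",
                    "remission", "dr", "cost_first_year", "cost_prevalent",
                    "cost_last6m", "rr_per_unit", "trend_inc", "trend_cf",
                    "trend_rem")

# Numbers are written with 17 significant digits so the text round-trip
# reproduces the doubles exactly.
write_schema_csv <- function(df, path) {
  out <- data.table::as.data.table(df)
  for (cl in names(out)) {
    if (is.double(out[[cl]])) {
      out[[cl]] <- formatC(out[[cl]], digits = 17, format = "g")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

read_schema_csv <- function(path, expected_cols, file_label) {
  if (!file.exists(path)) {
    stop("schema error: missing file ", file_label)
  }
  df <- data.table::as.data.table(
    utils::read.csv(path, stringsAsFactors = FALSE))
  missing <- setdiff(expected_cols, names(df))
  if (length(missing) > 0) {
    stop("schema error in ", file_label, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), expected_cols)
  if (length(extra) > 0) {
    stop("schema error in ", file_label, ": unexpected column(s) ",
         paste(extra, collapse = ", "))
  }
  data.table::setcolorder(df, expected_cols)
  int_cols <- intersect(c("age", "age_lo", "age_hi"), names(df))
  for (cl in int_cols) df[[cl]] <- as.integer(df[[cl]])
  num_cols <- setdiff(expected_cols, c(int_cols, "sex", "ethnicity"))
  for (cl in num_cols) df[[cl]] <- as.double(df[[cl]])
  df[]
}

#' Write / read a baseline dataset as a directory of CSV files
#'
#' Persists every component of a [generate_baseline()] dataset as plain-text
#' CSV (one `disease_<name>.csv` per disease, plus a `config.yaml` with the
#' generator settings). `read_dataset()` restores an identical object:
#' `read_dataset(write_dataset(ds, dir))` equals `ds`.
#'
#' @param ds A `baseline_dataset`.
#' @param directory Target (created if absent) / source directory.
#' @return `write_dataset()` the directory path invisibly; `read_dataset()`
#'   a `baseline_dataset`.
#' @export
write_dataset <- function(ds, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(DATASET_SCHEMAS)) {
    write_schema_csv(ds[[nm]], file.path(directory, paste0(nm, ".csv")))
  }
  for (dn in names(ds$diseases)) {
    write_schema_csv(ds$diseases[[dn]],
                     file.path(directory, paste0("disease_", dn, ".csv")))
  }
  yaml::write_yaml(c(list(base_year = ds$base_year), ds$config),
                   file.path(directory, "config.yaml"))
  invisible(directory)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(directory) {
  if (!dir.exists(directory)) stop("dataset directory not found: ", directory)
  parts <- lapply(names(DATASET_SCHEMAS), function(nm) {
    read_schema_csv(file.path(directory, paste0(nm, ".csv")),
                    DATASET_SCHEMAS[[nm]], paste0(nm, ".csv"))
  })
  names(parts) <- names(DATASET_SCHEMAS)
  disease_files <- sort(list.files(directory, pattern = "^disease_.*\\.csv$"))
  if (length(disease_files) == 0) stop("schema error: no disease_<name>.csv files")
  diseases <- lapply(disease_files, function(f) {
    read_schema_csv(file.path(directory, f), DISEASE_SCHEMA, f)
  })
  names(diseases) <- sub("^disease_(.*)\\.csv$", "\\1", disease_files)
  diseases <- diseases[c(intersect(DISEASE_NAMES, names(diseases)),
                         setdiff(names(diseases), DISEASE_NAMES))]
  cfgfile <- file.path(directory, "config.yaml")
  cfg <- if (file.exists(cfgfile)) yaml::read_yaml(cfgfile) else list()
  base_year <- cfg$base_year %||% BASE_YEAR
  cfg$base_year <- NULL
  structure(c(list(base_year = as.integer(base_year)),
              parts[c("population", "mortality", "pyld", "base_costs", "bmi",
                      "heights", "overweight")],
              list(diseases = diseases,
                   standard_population = parts$standard_population,
                   config = cfg)),
            class = "baseline_dataset")
}
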