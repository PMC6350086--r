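#' @importFrom data.table data.table as.data.table setkeyv := fwrite fread rbindlist setcolorder
#' @importFrom stats qnorm qbeta qgamma qlnorm qunif pnorm plnorm rnorm runif integrate quantile median sd cor dlnorm dnorm setNames
#' @importFrom utils modifyList
NULL

SEXES <- c("male", "female")
ETHNICITIES <- c("maori", "non_maori")
MAX_AGE <- 110L
BASE_YEAR <- 2011L
TREND_HORIZON <- 2026L

#' Enumerate the closed-cohort strata
#'
#' The model population is a closed cohort alive in the base year (2011),
#' cross-classified by sex, ethnicity (Maori / non-Maori) and single year of
#' age 0--110: 2 x 2 x 111 = 444 strata. Every input table and every model
#' output is indexed by these strata in this canonical order.
#'
#' @return A `data.table` with columns `sex`, `ethnicity`, `age0` (age in the
#'   base year) and the canonical row order (sex outer, then ethnicity, then
#'   age).
#' @export
strata_grid <- function() {
  dt <- data.table::CJ(sex = SEXES, ethnicity = ETHNICITIES, age0 = 0:MAX_AGE,
                       sorted = FALSE)
  dt[]
}

# integer id of the sex x ethnicity group (1..4), canonical order
group_index <- function(sex, ethnicity) {
  (match(sex, SEXES) - 1L) * 2L + match(ethnicity, ETHNICITIES)
}

group_grid <- function() {
  data.table::CJ(sex = SEXES, ethnicity = ETHNICITIES, sorted = FALSE)
}

# Build a [4 x 111] matrix (sex-ethnicity group x age) from a long table with
# columns sex, ethnicity, age, <value>. Errors if cells are missing.
group_age_matrix <- function(df, value_col) {
  m <- matrix(NA_real_, nrow = 4L, ncol = MAX_AGE + 1L)
  gi <- group_index(df$sex, df$ethnicity)
  m[cbind(gi, df$age + 1L)] <- df[[value_col]]
  if (anyNA(m)) {
    stop("incomplete table: missing (sex, ethnicity, age) cells for '",
         value_col, "'")
  }
  m
}

# Evaluate seeded code without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
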