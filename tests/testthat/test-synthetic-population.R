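test_that("stratum grid enumerates the closed cohort", {
  g <- strata_grid()
  expect_equal(nrow(g), 2 * 2 * 111)
  expect_equal(nrow(unique(g)), 444)
  expect_setequal(unique(g$sex), c("male", "female"))
  expect_setequal(unique(g$ethnicity), c("maori", "non_maori"))
  expect_equal(range(g$age0), c(0, 110))
})

test_that("generated dataset matches the configured population structure", {
  ds <- seed1_dataset()
  expect_equal(sum(ds$population$count), 4.4e6, tolerance = 1e-3)
  maori <- ds$population$ethnicity == "maori"
  share <- sum(ds$population$count[maori]) / sum(ds$population$count)
  expect_lt(abs(share - 0.15), 0.005)

  ds7 <- generate_baseline(generator_config(maori_share = 0.15), seed = 7)
  maori7 <- ds7$population$ethnicity == "maori"
  share7 <- sum(ds7$population$count[maori7]) / sum(ds7$population$count)
  expect_lt(abs(share7 - 0.15), 0.005)
})

test_that("generation is deterministic and seed-sensitive", {
  a <- generate_baseline(generator_config(total_population = 2e5), seed = 11)
  b <- generate_baseline(generator_config(total_population = 2e5), seed = 11)
  c <- generate_baseline(generator_config(total_population = 2e5), seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$diseases$chd$incidence, c$diseases$chd$incidence))
})

test_that("generated datasets pass the coherence check across seeds", {
  for (s in 1:3) {
    ds <- if (s == 1) seed1_dataset() else generate_baseline(seed = s)
    expect_length(coherence_check(ds), 0)
  }
})

test_that("coherence check flags planted violations", {
  ds <- generate_baseline(generator_config(total_population = 2e5), seed = 3)
  bad <- ds
  bad$diseases$stroke <- data.table::copy(ds$diseases$stroke)
  bad$diseases$stroke$remission <- 0.1
  v <- coherence_check(bad)
  expect_true(any(grepl("noncancer remission nonzero: stroke", v)))

  bad2 <- ds
  bad2$diseases$chd <- data.table::copy(ds$diseases$chd)
  bad2$diseases$chd$incidence[5] <- 1.5
  expect_true(any(grepl("rate out of range", coherence_check(bad2))))

  bad3 <- ds
  bad3$mortality <- data.table::copy(ds$mortality)
  bad3$mortality$acm_rate <- 1e-6
  expect_true(any(grepl("disease deaths exceed all-cause mortality",
                        coherence_check(bad3))))
})

test_that("doubling population scale doubles counts and leaves rates alone", {
  a <- generate_baseline(generator_config(total_population = 2e5), seed = 5)
  b <- generate_baseline(generator_config(total_population = 4e5), seed = 5)
  expect_equal(b$population$count, 2 * a$population$count, tolerance = 1e-2)
  expect_identical(a$mortality, b$mortality)
  expect_identical(a$diseases, b$diseases)
  expect_identical(a$bmi, b$bmi)
})

test_that("mortality is non-decreasing above age 60 and Maori exceed non-Maori", {
  ds <- seed1_dataset()
  m <- ds$mortality
  for (s in c("male", "female")) for (e in c("maori", "non_maori")) {
    r <- m[m$sex == s & m$ethnicity == e & m$age >= 60, ]
    r <- r[order(r$age), ]
    expect_true(all(diff(r$acm_rate) >= -1e-15))
  }
  wide <- merge(m[m$ethnicity == "maori", c("sex", "age", "acm_rate")],
                m[m$ethnicity == "non_maori", c("sex", "age", "acm_rate")],
                by = c("sex", "age"), suffixes = c("_ma", "_nm"))
  wide <- wide[wide$age < 110, ]  # both close at the terminal age
  expect_true(all(wide$acm_rate_ma >= wide$acm_rate_nm))
})

test_that("generator config rejects invalid scale and share", {
  expect_error(generator_config(total_population = 0), "positive")
  expect_error(generator_config(maori_share = 0), "share")
  expect_error(generator_config(maori_share = 1.2), "share")
})

test_that("dataset round-trips through CSV exactly", {
  ds <- generate_baseline(generator_config(total_population = 2e5), seed = 2)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  ds2 <- read_dataset(dir)
  expect_equal(ds2, ds)
  expect_identical(ds2$diseases$chd$incidence, ds$diseases$chd$incidence)
})

test_that("dataset reader reports schema problems by file and column", {
  ds <- generate_baseline(generator_config(total_population = 2e5), seed = 2)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  file.remove(file.path(dir, "population.csv"))
  expect_error(read_dataset(dir), "population.csv")

  dir2 <- withr::local_tempdir()
  write_dataset(ds, dir2)
  p <- utils::read.csv(file.path(dir2, "mortality.csv"))
  p$acm_rate <- NULL
  utils::write.csv(p, file.path(dir2, "mortality.csv"), row.names = FALSE)
  expect_error(read_dataset(dir2), "mortality.csv.*acm_rate")
})

test_that("a hand-edited cell changes only that cell after re-reading", {
  ds <- generate_baseline(generator_config(total_population = 2e5), seed = 2)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  f <- file.path(dir, "disease_chd.csv")
  tab <- utils::read.csv(f)
  tab$incidence[50] <- 0.123
  write.csv(tab, f, row.names = FALSE)
  ds2 <- read_dataset(dir)
  expect_equal(ds2$diseases$chd$incidence[50], 0.123)
  expect_equal(ds2$diseases$chd$incidence[-50], ds$diseases$chd$incidence[-50])
  expect_equal(ds2$mortality, ds$mortality)
})
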