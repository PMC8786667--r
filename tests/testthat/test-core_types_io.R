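test_that("cause taxonomies enforce the age-group cause lists and base cause", {
  tax <- cause_taxonomy("neonatal")
  expect_setequal(tax$causes,
                  c("tetanus", "lower_respiratory_infections", "preterm",
                    "intrapartum", "sepsis_meningitis", "congenital",
                    "diarrhoea", "other"))
  expect_true(tax$base_cause %in% tax$causes)
  expect_error(cause_taxonomy("neonatal", causes = c("preterm", "other")),
               "must contain")
  expect_error(cause_taxonomy("neonatal", base_cause = "nonexistent"),
               "not in the cause list")
  expect_error(
    cause_taxonomy("neonatal",
                   causes = c(default_causes_dup <- c(
                     "tetanus", "lower_respiratory_infections", "preterm",
                     "intrapartum", "sepsis_meningitis", "congenital",
                     "diarrhoea", "other", "other"))),
    "unique")
})

test_that("model taxonomies fix the reference cause per stratum", {
  expect_identical(model_taxonomy("neonatal", "low")$base_cause, "preterm")
  expect_identical(model_taxonomy("neonatal", "high")$base_cause,
                   "intrapartum")
  expect_identical(model_taxonomy("child_1to59m", "low")$base_cause,
                   "lower_respiratory_infections")
  expect_identical(model_taxonomy("child_1to59m", "high")$base_cause,
                   "lower_respiratory_infections")
})

test_that("pipeline config validates its invariants", {
  cfg <- pipeline_config()
  expect_lte(cfg$sigma_bound_high, 0.14)
  expect_lt(cfg$thresholds$neonatal[["low"]],
            cfg$thresholds$neonatal[["high"]])
  expect_error(pipeline_config(sigma_bound_high = 0.2))
  expect_error(pipeline_config(lambda_grid = c(2, 1)))
  expect_error(pipeline_config(thresholds = list(
    neonatal = c(low = 20, high = 10),
    child_1to59m = c(low = 25, high = 35))))
})

test_that("config round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("lambda_grid: [1, 2, 4]",
               "sigma_bound_high: 0.1",
               "seed: 42"), path)
  cfg <- read_config(path)
  expect_equal(cfg$lambda_grid, c(1, 2, 4))
  expect_equal(cfg$sigma_bound_high, 0.1)
  expect_equal(cfg$seed, 42L)
  writeLines("not_a_field: 3", path)
  expect_error(read_config(path), "unknown config fields")
})

test_that("studies read back with totals equal to the sum of counts", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "study_id,country,midyear,age_group,reported_cause,deaths,nationally_representative,source_type,cov_x1",
    "s1,KEN,2010,child_1to59m,lower_respiratory_infections,10,TRUE,va_study,0.5",
    "s1,KEN,2010,child_1to59m,diarrhoea,5,TRUE,va_study,0.5",
    "s1,KEN,2010,child_1to59m,other,5,TRUE,va_study,0.5"), path)
  studies <- read_studies(path, cause_taxonomy("child_1to59m"))
  expect_length(studies, 1L)
  expect_equal(studies[[1L]]$total_deaths, 20L)
  expect_equal(sum(studies[[1L]]$deaths), studies[[1L]]$total_deaths)
  expect_equal(studies[[1L]]$covariates, c(x1 = 0.5))
  expect_true(studies[[1L]]$nationally_representative)
})

test_that("study files with defects are rejected with context", {
  path <- withr::local_tempfile(fileext = ".csv")
  header <- "study_id,country,midyear,age_group,reported_cause,deaths"
  writeLines(c(header,
               "s1,KEN,2010,child_1to59m,diarrhoea,5",
               "s1,KEN,2010,child_1to59m,diarrhoea,7"), path)
  expect_error(read_studies(path, cause_taxonomy("child_1to59m")),
               "s1 / diarrhoea")
  writeLines(c(header, "s1,KEN,2010,child_1to59m,diarrhoea,-5"), path)
  expect_error(read_studies(path, cause_taxonomy("child_1to59m")),
               "row 1")
  writeLines(c(header, "s1,kenya,2010,child_1to59m,diarrhoea,5"), path)
  expect_error(read_studies(path, cause_taxonomy("child_1to59m")),
               "country code")
  writeLines(header, path)
  expect_warning(studies <- read_studies(path, cause_taxonomy("child_1to59m")),
                 "no rows")
  expect_length(studies, 0L)
})

test_that("studies round-trip through write_studies", {
  b <- generate_input_bundle(n_studies = 5L, deaths_per_study = 200L,
                             seed = 11L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_studies(b$studies, path)
  back <- read_studies(path, model_taxonomy("child_1to59m"))
  expect_length(back, 5L)
  for (i in seq_along(back)) {
    expect_equal(as.numeric(back[[i]]$deaths),
                 as.numeric(b$studies[[i]]$deaths))
    expect_equal(back[[i]]$covariates, b$studies[[i]]$covariates)
  }
})

test_that("envelope reading computes rates and validates inputs", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country,year,age_group,deaths,livebirths",
               "KEN,2010,neonatal,1000,100000",
               "KEN,2011,neonatal,0,100000"), path)
  env <- read_envelopes(path)
  expect_equal(env$rate, c(10, 0))
  writeLines(c("country,year,age_group,deaths,livebirths",
               "KEN,2010,neonatal,1000,0"), path)
  expect_error(read_envelopes(path), "livebirths")
})

test_that("estimates round-trip losslessly and normalise within country-year", {
  set.seed(5)
  frac <- prop.table(runif(10))
  est <- data.frame(country = "KEN", year = 2010L, age_group = "neonatal",
                    cause = paste0("c", 1:10),
                    fraction = frac, deaths = frac * 1234.567,
                    rate = frac * 12.3, lower = frac * 1000,
                    upper = frac * 1500, stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_estimates(est, path)
  back <- read_estimates(path)
  expect_identical(back$fraction, est$fraction)
  expect_identical(back$deaths, est$deaths)
  expect_identical(back$upper, est$upper)
  expect_lt(abs(sum(back$fraction) - 1), 1e-9)
  # empty estimates produce a header-only file
  write_estimates(est[0, ], path)
  expect_equal(nrow(read_estimates(path)), 0L)
})
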