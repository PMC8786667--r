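test_that("degenerate sources produce identical draws equal to the point run", {
  frac <- matrix(rep(c(0.6, 0.4), each = 50), 50L, 2L,
                 dimnames = list(NULL, c("a", "b")))
  draws <- propagate_draws(frac, envelope_deaths = 1000,
                           exogenous = c(measles = 100),
                           n_draws = 50L, seed = 1L)
  expect_equal(nrow(unique(draws)), 1L)
  expect_equal(draws[1L, ],
               postprocess_chain(frac[1L, ], 1000,
                                 exogenous = c(measles = 100)))
  expect_error(propagate_draws(frac, 1000, n_draws = 0L, seed = 1L),
               "positive")
})

test_that("lognormal envelope uncertainty propagates into the death CV", {
  frac <- matrix(rep(c(0.6, 0.4), each = 2000), 2000L, 2L,
                 dimnames = list(NULL, c("a", "b")))
  draws <- propagate_draws(frac, envelope_deaths = 1000,
                           envelope_sd_log = 0.1, n_draws = 2000L,
                           seed = 2L)
  for (j in 1:2) {
    cv <- sd(draws[, j]) / mean(draws[, j])
    expect_equal(cv, sqrt(exp(0.1^2) - 1), tolerance = 0.1)
  }
  expect_identical(draws,
                   propagate_draws(frac, 1000, envelope_sd_log = 0.1,
                                   n_draws = 2000L, seed = 2L))
})

test_that("uncertainty ranges use the documented percentile convention", {
  expect_equal(uncertainty_range(1:1000),
               c(lower = 25.975, upper = 975.025))
  expect_equal(uncertainty_range(rep(7, 50)), c(lower = 7, upper = 7))
  expect_error(uncertainty_range(1:10), "at least 40")
  set.seed(4)
  for (i in 1:20) {
    x <- stats::rlnorm(200)
    ur <- uncertainty_range(x)
    expect_gte(mean(x), ur[["lower"]] * 0.999)
    expect_gte(median(x), ur[["lower"]])
    expect_lte(median(x), ur[["upper"]])
  }
})

test_that("uncertainty ranges widen when a variance source grows", {
  frac <- matrix(rep(c(0.7, 0.3), each = 500), 500L, 2L,
                 dimnames = list(NULL, c("a", "b")))
  narrow <- propagate_draws(frac, 1000, envelope_sd_log = 0.05,
                            exogenous = c(measles = 100),
                            exogenous_sd_log = 0.05,
                            n_draws = 500L, seed = 5L)
  wide <- propagate_draws(frac, 1000, envelope_sd_log = 0.15,
                          exogenous = c(measles = 100),
                          exogenous_sd_log = 0.2,
                          n_draws = 500L, seed = 5L)
  for (cz in colnames(narrow)) {
    urn <- uncertainty_range(narrow[, cz])
    urw <- uncertainty_range(wide[, cz])
    expect_gt(urw[["upper"]] - urw[["lower"]],
              urn[["upper"]] - urn[["lower"]])
  }
})

test_that("regional aggregation sums draws before percentiles", {
  draws_a <- matrix(c(100, 110, 90), 3L, 1L, dimnames = list(NULL, "a"))
  draws_b <- matrix(c(200, 190, 210), 3L, 1L, dimnames = list(NULL, "a"))
  lookup <- data.frame(country = c("KEN", "TZA"),
                       region = "Eastern and Southern Africa")
  agg <- aggregate_region_draws(list(KEN = draws_a, TZA = draws_b), lookup)
  expect_equal(agg[["Eastern and Southern Africa"]][, "a"],
               c(300, 300, 300))
  expect_equal(agg$global, agg[["Eastern and Southern Africa"]])
  expect_error(aggregate_region_draws(list(XXX = draws_a), lookup),
               "not mapped")
})

test_that("regional point aggregation keeps fractions inside member range", {
  est <- data.frame(
    country = rep(c("KEN", "TZA", "NGA"), each = 2L),
    year = 2019L, age_group = "child_1to59m",
    cause = rep(c("malaria", "other"), 3L),
    deaths = c(30, 70, 60, 40, 50, 50),
    fraction = c(0.3, 0.7, 0.6, 0.4, 0.5, 0.5),
    rate = 0, lower = 0, upper = 0)
  agg <- aggregate_region(est)
  esa <- agg[agg$region == "Eastern and Southern Africa" &
               agg$cause == "malaria", ]
  expect_equal(esa$deaths, 90)
  expect_equal(esa$fraction, 90 / 200)
  expect_gte(esa$fraction, 0.3)
  expect_lte(esa$fraction, 0.6)
  # the global total over regions equals the country total
  expect_equal(sum(agg$deaths), sum(est$deaths))
})

test_that("rates, ARR, and SDG projections follow their closed forms", {
  expect_equal(cause_rate(0.94e6, 139.9e6), 6.72, tolerance = 1e-3)
  expect_equal(cause_rate(0, 1000), 0)
  expect_equal(cause_rate(100, 2000), cause_rate(100, 1000) / 2)
  expect_error(cause_rate(10, 0), "positive")

  expect_equal(annual_rate_reduction(10, 5, 2000, 2015),
               100 * log(2) / 15)
  expect_equal(annual_rate_reduction(7, 7, 2000, 2019), 0)
  expect_lt(annual_rate_reduction(5, 10, 2015, 2019), 0)
  expect_error(annual_rate_reduction(0, 5, 2000, 2015), "undefined")

  rates <- c(malaria = 10, other = 40)
  proj <- sdg_projection(rates, arr = c(malaria = 0, other = 5),
                         current_year = 2019L, target_year = 2030L,
                         target_all_cause = 25)
  expect_equal(proj$required, c(0.2, 0.8) * 25)
  expect_equal(proj$projected[1L], 10)  # zero ARR: projection is flat
  # an ARR exactly closing the gap lands on the requirement
  arr_exact <- 100 * log(10 / 5) / 11
  p2 <- sdg_projection(c(malaria = 10, other = 40),
                       arr = c(malaria = arr_exact, other = 0),
                       target_all_cause = 25)
  expect_equal(p2$projected[1L], p2$required[1L])
})

test_that("country-year summaries land in the estimates schema", {
  set.seed(6)
  draws <- cbind(a = stats::rlnorm(200, log(500), 0.1),
                 b = stats::rlnorm(200, log(300), 0.1))
  est <- summarise_country_year(draws, "KEN", 2019L, "neonatal",
                                livebirths = 1e5)
  expect_setequal(names(est), c("country", "year", "age_group", "cause",
                                "fraction", "deaths", "rate", "lower",
                                "upper"))
  expect_equal(sum(est$fraction), 1)
  expect_true(all(est$lower <= est$deaths & est$deaths <= est$upper))
  expect_equal(est$rate, est$deaths / 1e5 * 1000)
})
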