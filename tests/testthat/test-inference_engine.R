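test_that("linear predictor follows the contrast parameterisation", {
  beta <- matrix(0, 3L, 2L)
  u <- rep(0, 3L)
  expect_equal(linear_predictor(beta, u, c(1, 2)), rep(0, 3L))
  beta[2L, ] <- c(0, 1)
  expect_equal(linear_predictor(beta, u, c(1, 2))[2L], 2)
  expect_error(linear_predictor(beta, u, c(1, NA)), "non-finite")
  # a random effect of 0.14 multiplies the cause's odds by exp(0.14)
  u2 <- c(0, 0.14, 0)
  p0 <- softmax_fractions(linear_predictor(beta, u, c(1, 0)))
  p1 <- softmax_fractions(linear_predictor(beta, u2, c(1, 0)))
  odds0 <- p0[2L] / p0[1L]
  odds1 <- p1[2L] / p1[1L]
  expect_equal(odds1 / odds0, exp(0.14))
})

test_that("softmax fractions are normalised, exact, and shift-invariant", {
  expect_equal(softmax_fractions(rep(0, 5L)), rep(0.2, 5L))
  expect_equal(softmax_fractions(c(0, log(3))), c(0.25, 0.75))
  set.seed(1)
  for (i in 1:50) {
    eta <- rnorm(sample(2:8, 1L), sd = 3)
    p <- softmax_fractions(eta)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(softmax_fractions(eta + 123.4), p, tolerance = 1e-12)
  }
  # overflow safety
  expect_equal(sum(softmax_fractions(c(1000, 1001))), 1)
})

test_that("log likelihood matches the hand-computed multinomial pmf", {
  tax <- toy_taxonomy(c("A", "B"))
  st <- toy_study(c(A = 1, B = 1))
  G <- build_misclass_matrix(tax, c("A", "B"))
  params <- list(beta = matrix(0, 2L, 1L))
  # log[ 2!/(1!1!) * 0.5^2 ] = -log 2
  expect_equal(log_likelihood(params, list(st), list(G)), -log(2))
  # all-zero counts give an empty product
  st0 <- toy_study(c(A = 0, B = 0))
  expect_equal(log_likelihood(params, list(st0), list(G)), 0)
})

test_that("aggregated likelihood equals the reduced multinomial, exhaustively", {
  # brute-force oracle: for every count vector with N <= 6 on J reported
  # categories, the model likelihood with aggregation matrix G must equal
  # dmultinom on the merged probabilities.
  set.seed(99)
  for (C in 2:4) {
    causes <- LETTERS[1:C]
    for (J in 1:min(C, 3L)) {
      assign <- c(sample.int(J), sample.int(J, C - J, replace = TRUE))
      reported <- paste0("r", sort(unique(assign)))
      mapping <- stats::setNames(paste0("r", assign), causes)
      tax <- toy_taxonomy(causes)
      G <- build_misclass_matrix(tax, reported, mapping)
      beta <- matrix(0, C, 1L)
      beta[-1L, 1L] <- rnorm(C - 1L)
      p <- softmax_fractions(as.numeric(beta))
      q <- aggregate_probs(G, p)
      for (N in 0:6) {
        counts <- compositions(N, J)
        for (i in seq_len(nrow(counts))) {
          y <- stats::setNames(counts[i, ], reported)
          st <- toy_study(y)
          ll <- log_likelihood(list(beta = beta), list(st), list(G))
          expect_equal(ll, stats::dmultinom(counts[i, ], prob = q,
                                            log = TRUE),
                       tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("likelihood flags impossible counts", {
  tax <- toy_taxonomy(c("A", "B", "C", "other"))
  st <- toy_study(c(A = 5, other = 1))
  G <- build_misclass_matrix(tax, c("A", "other"))
  # log odds extreme enough that cause A's probability underflows to zero
  beta <- matrix(c(0, 800, -800, -800), 4L, 1L)
  expect_warning(
    ll <- log_likelihood(list(beta = beta), list(st), list(G)),
    "zero reported-category probability")
  expect_identical(ll, -Inf)
})

test_that("the Laplace prior scales with lambda and spares intercepts", {
  beta <- matrix(c(0, 0, 0.3, -0.5, 1.2, 0.7), 3L, 2L, byrow = TRUE)
  params1 <- list(beta = beta, sigma = 0.07)
  lp1 <- log_prior(params1, lambda = 1, base = 1L)
  lp2 <- log_prior(params1, lambda = 2, base = 1L)
  # penalised part: -lambda * sum|slopes|; normalising constant log(lambda/2)
  n_slopes <- 2L
  sum_abs <- abs(-0.5) + abs(0.7)
  expect_equal((lp2 - n_slopes * log(2 / 2)) - (lp1 - n_slopes * log(1 / 2)),
               -(2 - 1) * sum_abs)
  # intercepts do not enter the penalised part
  beta2 <- beta
  beta2[, 1L] <- beta2[, 1L] + 0.9
  lp1b <- log_prior(list(beta = beta2, sigma = 0.07), lambda = 1, base = 1L)
  d_norm <- sum(stats::dnorm(beta2[-1L, 1L], 0, 10, log = TRUE)) -
    sum(stats::dnorm(beta[-1L, 1L], 0, 10, log = TRUE))
  expect_equal(lp1b - lp1, d_norm)
  # the random-effect SD bound is hard
  expect_identical(log_prior(list(beta = beta, sigma = 0.15),
                             lambda = 1, sigma_bound = 0.14), -Inf)
  expect_true(is.finite(log_prior(list(beta = beta, sigma = 0.14),
                                  lambda = 1, sigma_bound = 0.14)))
})

test_that("posterior sampling is reproducible bit for bit", {
  b <- generate_input_bundle(n_studies = 6L, deaths_per_study = 300L,
                             seed = 21L)
  tax <- model_taxonomy("child_1to59m")
  cfg <- pipeline_config(chains = 2L, iterations = 100L, burnin = 100L,
                         seed = 5L)
  f1 <- sample_posterior(b$studies, b$matrices, tax, cfg, lambda = 2)
  f2 <- sample_posterior(b$studies, b$matrices, tax, cfg, lambda = 2)
  expect_identical(f1$chains, f2$chains)
  expect_true(all(sigma_draws(f1) > 0))
  expect_true(all(sigma_draws(f1) <= cfg$sigma_bound_high))
})

test_that("null data keep non-intercept coefficients near zero", {
  tax <- toy_taxonomy(c("A", "B", "C", "D"))
  truth <- make_ground_truth(tax, n_covariates = 3L, n_nonzero = 0L,
                             sigma = 0.05, seed = 31L)
  covs <- generate_covariates(8L, 5L, 3L, seed = 32L)
  sim <- generate_studies(truth, covs, study_sizes = rep(1500L, 12L),
                          seed = 33L)
  fit <- sample_posterior(sim$studies, sim$matrices, tax, fast_config(),
                          lambda = 2)
  d <- fit_draws(fit)
  slope_cols <- grep("^beta\\[.*,cov_", colnames(d))
  for (j in slope_cols) {
    expect_lt(abs(mean(d[, j])), 3 * sd(d[, j]))
  }
})

test_that("two-cause single-study posterior matches the conjugate oracle", {
  # With an intercept-only two-cause model, a weak prior, and sigma pinned
  # near zero, the posterior cause fraction should match the Beta(y1, y2)
  # posterior implied by a flat prior on the log odds.
  tax <- toy_taxonomy(c("A", "B"))
  st <- toy_study(c(A = 30, B = 70))
  G <- build_misclass_matrix(tax, c("A", "B"))
  cfg <- pipeline_config(chains = 2L, iterations = 2000L, burnin = 1000L,
                         seed = 9L, sigma_bound_low = 1e-4)
  fit <- sample_posterior(list(st), list(G), tax, cfg, lambda = 1,
                          sigma_bound = cfg$sigma_bound_low)
  # fraction draws for cause B (eta_B = intercept draw)
  eta <- fit_draws(fit)[, "beta[B,(Intercept)]"]
  pB <- exp(eta) / (1 + exp(eta))
  oracle_mean <- 70 / 100              # Beta(70, 30) mean under Haldane prior
  oracle_sd <- sqrt(0.7 * 0.3 / 101)
  expect_lt(abs(mean(pB) - oracle_mean), 0.02)
  expect_lt(abs(sd(pB) - oracle_sd), 0.015)
})

test_that("Gelman-Rubin diagnostics behave as the PSRF formula predicts", {
  set.seed(77)
  iid <- lapply(1:4, function(i) matrix(rnorm(5000), ncol = 1L,
                                        dimnames = list(NULL, "theta")))
  expect_lt(gelman_rubin(iid)[["theta"]], 1.05)
  shifted <- iid
  shifted[[1L]] <- shifted[[1L]] + 10
  expect_gt(gelman_rubin(shifted)[["theta"]], 1.5)
  const <- lapply(1:3, function(i) matrix(1, 100L, 1L,
                                          dimnames = list(NULL, "c")))
  expect_equal(gelman_rubin(const)[["c"]], 1)
  expect_error(gelman_rubin(iid[1L]), "at least 2 chains")
})

test_that("draws and diagnostics serialise to columnar text files", {
  b <- generate_input_bundle(n_studies = 4L, deaths_per_study = 200L,
                             seed = 41L)
  tax <- model_taxonomy("child_1to59m")
  cfg <- pipeline_config(chains = 2L, iterations = 50L, burnin = 50L,
                         seed = 3L)
  fit <- sample_posterior(b$studies, b$matrices, tax, cfg, lambda = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, path)
  d <- utils::read.csv(path)
  expect_setequal(names(d), c("parameter", "chain", "iteration", "value"))
  expect_equal(nrow(d), 2L * 50L * length(fit$param_names))
  rpt <- write_diagnostics(fit, path)
  expect_true(all(c("gelman_rubin", "mean_acceptance") %in% names(rpt)))
})
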