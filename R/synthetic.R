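#' Generate a standardized country-year covariate panel
#'
#' Covariates evolve as stationary AR(1) processes within country (smooth in
#' time, like the health and development indicators the real model projects
#' causes on) and are standardized to mean 0, SD 1 over the whole panel.
#'
#' @param n_countries,n_years,n_covariates Panel dimensions (positive).
#' @param seed Integer seed.
#' @param rho Lag-1 autocorrelation within country (0 gives white noise).
#' @param start_year First calendar year.
#' @return Data.frame with `country`, `year`, and columns `cov_1 ...
#'   cov_K`.
#' @export
generate_covariates <- function(n_countries, n_years, n_covariates, seed,
                                rho = 0.85, start_year = 2000L) {
  stopifnot(n_countries > 0, n_years > 0, n_covariates > 0)
  set.seed(seed)
  countries <- synth_iso3(n_countries)
  years <- start_year + seq_len(n_years) - 1L
  out <- expand.grid(year = years, country = countries,
                     KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)[, c("country", "year")]
  for (k in seq_len(n_covariates)) {
    z <- matrix(0, n_years, n_countries)
    innov_sd <- sqrt(1 - min(rho, 0.999)^2)
    z[1L, ] <- stats::rnorm(n_countries)
    if (n_years > 1L) {
      for (t in 2:n_years) {
        z[t, ] <- rho * z[t - 1L, ] + stats::rnorm(n_countries, 0, innov_sd)
      }
    }
    v <- as.numeric(z)
    out[[paste0("cov_", k)]] <- (v - mean(v)) / stats::sd(v)
  }
  out
}

synth_iso3 <- function(n) sprintf("S%02d", seq_len(n))

#' Construct a sparse ground truth for simulation
#'
#' Builds the generating parameters of the multinomial-logit model: a
#' coefficient matrix with a chosen number of truly nonzero covariate
#' effects (the rest exactly zero, which the LASSO should recover), and the
#' study random-effect SD.
#'
#' @param taxonomy A `cause_taxonomy`.
#' @param n_covariates Number of covariates K.
#' @param n_nonzero Number of covariates with a real effect (applied to
#'   every non-base cause, with alternating sign across causes).
#' @param effect_size Absolute value of the nonzero coefficients.
#' @param intercepts Optional length-C vector of intercepts (base entry
#'   ignored); default draws them from N(0, 0.5) so baseline fractions
#'   differ by cause.
#' @param sigma True random-effect SD.
#' @param seed Integer seed.
#' @return A list of class `ground_truth` with `beta` (causes x (1+K), base
#'   row zero), `sigma`, `nonzero` (covariate indices), plus slots filled by
#'   [generate_studies()].
#' @export
make_ground_truth <- function(taxonomy, n_covariates, n_nonzero = 2L,
                              effect_size = 0.8, intercepts = NULL,
                              sigma = 0.14, seed = 1L) {
  stopifnot(n_nonzero <= n_covariates, sigma >= 0)
  set.seed(seed)
  C <- n_causes(taxonomy)
  base <- base_index(taxonomy)
  beta <- matrix(0, C, n_covariates + 1L,
                 dimnames = list(taxonomy$causes,
                                 c("(Intercept)",
                                   paste0("cov_", seq_len(n_covariates)))))
  if (is.null(intercepts)) intercepts <- stats::rnorm(C, 0, 0.5)
  beta[, 1L] <- intercepts
  beta[base, ] <- 0
  nonzero <- seq_len(n_nonzero)
  for (k in nonzero) {
    signs <- rep_len(c(1, -1), C)
    beta[-base, k + 1L] <- signs[-base] * effect_size
  }
  structure(list(taxonomy = taxonomy, beta = beta, sigma = sigma,
                 nonzero = nonzero, study_effects = NULL,
                 true_fractions = NULL),
            class = "ground_truth")
}

#' Simulate study datasets from the generating model
#'
#' For each study: a covariate row is assigned, a study random-effect vector
#' is drawn from N(0, sigma) per non-base cause contrast, true-cause
#' fractions follow the softmax model, counts are drawn multinomially on the
#' study's reported categories after aggregation through its
#' misclassification matrix. The ground truth (random effects and true
#' fractions) is returned alongside the data.
#'
#' @param truth A `ground_truth` from [make_ground_truth()].
#' @param covariates Covariate panel from [generate_covariates()].
#' @param study_sizes Integer vector of total deaths per study.
#' @param reporting_patterns List (recycled over studies) of reporting
#'   specifications: each either `NULL` (full reporting) or a list with
#'   `reported` (character vector of categories) and optionally `mapping`
#'   (named true cause -> category; defaults to the residual-category
#'   convention).
#' @param seed Integer seed.
#' @param representative Logical vector (recycled) flagging nationally
#'   representative studies.
#' @return List with `studies` (list of `study_dataset`), `matrices`
#'   (their `misclass_matrix` objects), and `truth` completed with
#'   `study_effects` and `true_fractions`.
#' @export
generate_studies <- function(truth, covariates, study_sizes,
                             reporting_patterns = list(NULL), seed = 1L,
                             representative = FALSE) {
  set.seed(seed)
  taxonomy <- truth$taxonomy
  C <- n_causes(taxonomy)
  base <- base_index(taxonomy)
  S <- length(study_sizes)
  cov_cols <- grep("^cov_", names(covariates), value = TRUE)
  stopifnot(length(cov_cols) + 1L == ncol(truth$beta))
  rows <- sample.int(nrow(covariates), S, replace = TRUE)
  representative <- rep_len(representative, S)
  patterns <- rep_len(reporting_patterns, S)

  studies <- vector("list", S)
  matrices <- vector("list", S)
  effects <- matrix(0, S, C, dimnames = list(NULL, taxonomy$causes))
  fractions <- matrix(0, S, C, dimnames = list(NULL, taxonomy$causes))
  for (s in seq_len(S)) {
    pat <- patterns[[s]]
    if (is.null(pat)) {
      reported <- taxonomy$causes
      mapping <- NULL
    } else {
      reported <- pat$reported
      mapping <- pat$mapping
    }
    G <- build_misclass_matrix(taxonomy, reported, mapping,
                               study_id = sprintf("study%03d", s))
    u_s <- rep(0, C)
    if (truth$sigma > 0) {
      u_s[-base] <- stats::rnorm(C - 1L, 0, truth$sigma)
    }
    x <- c(1, as.numeric(covariates[rows[s], cov_cols]))
    p <- softmax_fractions(linear_predictor(truth$beta, u_s, x))
    q <- aggregate_probs(G, p)
    y <- as.numeric(stats::rmultinom(1L, study_sizes[s], q))
    names(y) <- reported
    covs <- stats::setNames(x[-1L], cov_cols)
    studies[[s]] <- study_dataset(
      study_id = sprintf("study%03d", s),
      country = covariates$country[rows[s]],
      midyear = covariates$year[rows[s]],
      age_group = taxonomy$age_group,
      deaths = y,
      covariates = covs,
      nationally_representative = representative[s],
      source_type = "va_study")
    matrices[[s]] <- G
    effects[s, ] <- u_s
    fractions[s, ] <- p
  }
  truth$study_effects <- effects
  truth$true_fractions <- fractions
  list(studies = studies, matrices = matrices, truth = truth)
}

#' Generate smoothly declining all-cause mortality envelopes
#'
#' Country rates decline log-linearly from staggered starting levels chosen
#' so that the panel spans all mortality strata, with several countries
#' crossing strata thresholds over time (exercising model averaging).
#'
#' @param n_countries Number of countries.
#' @param years Integer vector of calendar years.
#' @param seed Integer seed.
#' @param age_group Age-group label for the rows.
#' @param rate_range `c(high, low)`: rates (deaths per 1000 livebirths) at
#'   the first year span up to `high` across countries and decline toward
#'   `low`.
#' @param livebirths Livebirths per country-year (recycled).
#' @param draw_sd_log SD on the log scale for envelope uncertainty draws.
#' @return Envelope data.frame (see [read_envelopes()] schema, `rate`
#'   included).
#' @export
generate_envelope_series <- function(n_countries, years, seed,
                                     age_group = "child_1to59m",
                                     rate_range = c(120, 15),
                                     livebirths = 1e5,
                                     draw_sd_log = 0.05) {
  set.seed(seed)
  countries <- synth_iso3(n_countries)
  start_rates <- exp(seq(log(rate_range[1L]), log(max(rate_range[2L], 1)),
                         length.out = n_countries))
  arr <- stats::runif(n_countries, 0.02, 0.06)  # annual decline rates
  out <- do.call(rbind, lapply(seq_len(n_countries), function(i) {
    t <- seq_along(years) - 1L
    rate <- start_rates[i] * exp(-arr[i] * t)
    lb <- rep_len(livebirths, length(years))
    data.frame(country = countries[i], year = years, age_group = age_group,
               deaths = rate * lb / 1000, livebirths = lb, rate = rate,
               draw_sd_log = draw_sd_log, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Generate exogenous single-cause series from envelopes
#'
#' Each exogenous cause receives a target share of the envelope deaths,
#' jittered lognormally (deaths are positive and their uncertainty ranges
#' asymmetric); the jitter SD is recorded in `draw_sd_log` for Monte-Carlo
#' propagation.
#'
#' @param envelopes Envelope data.frame.
#' @param shares Named numeric vector of target shares in `[0, 1)` per
#'   exogenous cause (names from the exogenous cause list); must sum to
#'   less than 1.
#' @param seed Integer seed.
#' @param jitter_sd_log Lognormal jitter SD.
#' @return Exogenous-series data.frame (see [read_exogenous()] schema).
#' @export
generate_exogenous_series <- function(envelopes, shares, seed,
                                      jitter_sd_log = 0.1) {
  stopifnot(all(shares >= 0), all(shares < 1))
  if (sum(shares) >= 1) {
    stop("exogenous cause shares must sum to less than 1 (got ",
         signif(sum(shares), 3), ")")
  }
  set.seed(seed)
  out <- do.call(rbind, lapply(names(shares), function(cz) {
    jitter <- if (shares[[cz]] > 0) {
      stats::rlnorm(nrow(envelopes), 0, jitter_sd_log)
    } else {
      rep(1, nrow(envelopes))
    }
    data.frame(country = envelopes$country, year = envelopes$year,
               age_group = envelopes$age_group, cause = cz,
               deaths = shares[[cz]] * envelopes$deaths * jitter,
               draw_sd_log = jitter_sd_log, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic input bundle
#'
#' Convenience wrapper producing covariates, ground truth, studies with
#' matrices, envelopes, and exogenous series under one seed — the default
#' desk-scale scenario used throughout the package's own validation.
#'
#' @param taxonomy A `cause_taxonomy`.
#' @param n_countries,n_years,n_covariates Panel dimensions.
#' @param n_studies Number of studies.
#' @param deaths_per_study Total deaths per study (recycled).
#' @param sigma True random-effect SD.
#' @param n_nonzero Truly nonzero covariate effects.
#' @param effect_size Absolute effect size of nonzero coefficients.
#' @param seed Integer seed.
#' @param partial_reporting Share of studies that pool some causes into
#'   their residual category.
#' @return List with `covariates`, `studies`, `matrices`, `truth`,
#'   `envelopes`, `exogenous`.
#' @export
generate_input_bundle <- function(taxonomy = model_taxonomy("child_1to59m"),
                                  n_countries = 15L, n_years = 20L,
                                  n_covariates = 5L, n_studies = 40L,
                                  deaths_per_study = 2000L,
                                  sigma = 0.14, n_nonzero = 2L,
                                  effect_size = 0.8, seed = 1L,
                                  partial_reporting = 0.3) {
  covs <- generate_covariates(n_countries, n_years, n_covariates, seed)
  truth <- make_ground_truth(taxonomy, n_covariates, n_nonzero, effect_size,
                             sigma = sigma, seed = seed + 1L)
  # some studies pool two non-base causes into "other"
  pooled <- setdiff(taxonomy$causes,
                    c(taxonomy$base_cause, "other"))[1:2]
  partial <- list(reported = setdiff(taxonomy$causes, pooled))
  n_partial <- round(partial_reporting * n_studies)
  patterns <- c(rep(list(partial), n_partial),
                rep(list(NULL), n_studies - n_partial))
  sim <- generate_studies(truth, covs,
                          study_sizes = rep_len(deaths_per_study, n_studies),
                          reporting_patterns = patterns, seed = seed + 2L,
                          representative = c(TRUE, rep(FALSE, n_studies - 1L)))
  env <- generate_envelope_series(n_countries, 2000:2019, seed + 3L,
                                  age_group = taxonomy$age_group)
  exo <- generate_exogenous_series(
    env, c(measles = 0.04, hiv = 0.02, tb_pulmonary = 0.01,
           tb_extrapulmonary = 0.005), seed + 4L)
  c(list(covariates = covs), sim, list(envelopes = env, exogenous = exo))
}
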