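#' Pipeline configuration
#'
#' Collects every tunable the estimation pipeline uses: the LASSO penalty
#' grid, the bound on the study random-effect SD (0.14 for high-mortality
#' models, small for low-mortality models), MCMC settings, the mortality-rate
#' strata thresholds per age group, vaccine-adjustment parameters, the cap on
#' exogenous single-cause totals, and the Monte-Carlo draw count for
#' uncertainty ranges.
#'
#' @param lambda_grid Ascending positive penalty values searched by
#'   cross-validation.
#' @param sigma_bound_high Upper bound on the random-effect SD in
#'   high-mortality models; at most 0.14 (a change in cause odds within about
#'   30\% for most studies).
#' @param sigma_bound_low Upper bound for low-mortality models, where random
#'   effects are restricted to be small.
#' @param chains,iterations,burnin MCMC settings: number of chains, kept
#'   iterations per chain after burn-in, and burn-in iterations.
#' @param seed Integer seed controlling all randomness.
#' @param thresholds Named list of `c(low, high)` rate thresholds (deaths per
#'   1000 livebirths) per age group: below `low` is the low stratum, at or
#'   above `high` is the high stratum, in between the two fitted models are
#'   averaged.
#' @param vaccine_params Named list per vaccine of
#'   `list(ve_paf = , cause = )`: vaccine efficacy times population
#'   attributable fraction and the cause it protects against.
#' @param exo_cap_share Maximum share of the envelope that exogenous
#'   single-cause series may occupy before pro-rata rescaling.
#' @param n_draws Monte-Carlo draws for uncertainty propagation.
#' @param cv_folds Number of leave-studies-out cross-validation folds.
#' @param cv_metric `"mae"` (default) or `"mse"` on reported-category
#'   fractions.
#' @param one_se_multiplier Multiplier on the standard error in the penalty
#'   selection rule (1 gives the one-SE rule).
#' @param intercept_sd Prior SD of the (unpenalised) intercepts.
#' @param init_retries Re-initialisation attempts if the posterior is
#'   non-finite at the starting point.
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(lambda_grid = c(0.5, 1, 2, 4, 8, 16),
                            sigma_bound_high = 0.14,
                            sigma_bound_low = 0.01,
                            chains = 4L,
                            iterations = 5000L,
                            burnin = 2500L,
                            seed = 1L,
                            thresholds = list(
                              neonatal = c(low = 10, high = 20),
                              child_1to59m = c(low = 25, high = 35)
                            ),
                            vaccine_params = list(
                              hib = list(ve_paf = 0.4,
                                         cause = "lower_respiratory_infections"),
                              pcv = list(ve_paf = 0.3,
                                         cause = "lower_respiratory_infections"),
                              rotavirus = list(ve_paf = 0.25,
                                               cause = "diarrhoea")
                            ),
                            exo_cap_share = 0.9,
                            n_draws = 500L,
                            cv_folds = 5L,
                            cv_metric = c("mae", "mse"),
                            one_se_multiplier = 1,
                            intercept_sd = 10,
                            init_retries = 5L) {
  cv_metric <- match.arg(cv_metric)
  stopifnot(
    is.numeric(lambda_grid), all(lambda_grid > 0),
    !is.unsorted(lambda_grid, strictly = TRUE),
    sigma_bound_high > 0, sigma_bound_high <= 0.14,
    sigma_bound_low > 0,
    chains >= 1, iterations >= 1, burnin >= 0,
    exo_cap_share > 0, exo_cap_share <= 1,
    n_draws >= 1, cv_folds >= 2, one_se_multiplier >= 0
  )
  for (th in thresholds) {
    stopifnot(length(th) == 2L, th[["low"]] < th[["high"]])
  }
  structure(
    list(lambda_grid = lambda_grid,
         sigma_bound_high = sigma_bound_high,
         sigma_bound_low = sigma_bound_low,
         chains = as.integer(chains),
         iterations = as.integer(iterations),
         burnin = as.integer(burnin),
         seed = as.integer(seed),
         thresholds = thresholds,
         vaccine_params = vaccine_params,
         exo_cap_share = exo_cap_share,
         n_draws = as.integer(n_draws),
         cv_folds = as.integer(cv_folds),
         cv_metric = cv_metric,
         one_se_multiplier = one_se_multiplier,
         intercept_sd = intercept_sd,
         init_retries = as.integer(init_retries)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields not present in the file keep their defaults; see
#' [pipeline_config()] for the schema.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$thresholds)) {
    raw$thresholds <- lapply(raw$thresholds, unlist)
  }
  do.call(pipeline_config, raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("u5cod pipeline configuration\n")
  cat("  lambda grid: ", paste(x$lambda_grid, collapse = ", "), "\n", sep = "")
  cat("  sigma bounds (high/low models): ", x$sigma_bound_high, " / ",
      x$sigma_bound_low, "\n", sep = "")
  cat("  MCMC: ", x$chains, " chains x ", x$iterations,
      " kept iterations (burn-in ", x$burnin, ")\n", sep = "")
  cat("  MC draws for uncertainty: ", x$n_draws, "\n", sep = "")
  invisible(x)
}
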