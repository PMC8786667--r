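#' Leave-studies-out cross-validation error for one penalty
#'
#' Studies are partitioned into folds (stratified by total deaths so folds
#' are balanced). For each fold the model is refit on the remaining studies
#' and each held-out study's empirical reported-category fractions are
#' compared with its predicted fractions `G p_hat`, where `p_hat` uses the
#' posterior-mean fixed effects and a random effect predicted at zero (the
#' study was unseen). The error is the mean absolute difference over
#' reported categories (or squared, per config).
#'
#' @param studies List of `study_dataset` objects.
#' @param matrices List of `misclass_matrix`, one per study.
#' @param taxonomy A `cause_taxonomy`.
#' @param lambda Penalty value to evaluate.
#' @param config A `pipeline_config`; `cv_folds`, `cv_metric`, and the MCMC
#'   settings apply.
#' @param sigma_bound Random-effect SD bound for the fits.
#' @return List with `mean` (mean error across folds), `se` (standard error
#'   across folds), and `fold_errors`.
#' @export
cv_error <- function(studies, matrices, taxonomy, lambda, config,
                     sigma_bound = config$sigma_bound_high) {
  S <- length(studies)
  n_folds <- config$cv_folds
  if (S < n_folds) {
    stop("fewer studies (", S, ") than folds (", n_folds, ")")
  }
  folds <- deal_folds(vapply(studies, `[[`, 1L, "total_deaths"), n_folds)
  fold_errors <- vapply(seq_len(n_folds), function(f) {
    train <- folds != f
    fit <- sample_posterior(studies[train], matrices[train], taxonomy,
                            config, lambda, sigma_bound)
    bhat <- apply(beta_draws(fit), c(2L, 3L), mean)
    errs <- vapply(which(!train), function(s) {
      st <- studies[[s]]
      x <- c(1, unname(st$covariates))
      p_hat <- softmax_fractions(
        linear_predictor(bhat, rep(0, nrow(bhat)), x))
      q_hat <- aggregate_probs(matrices[[s]], p_hat)
      q_emp <- as.numeric(st$deaths) / st$total_deaths
      if (config$cv_metric == "mae") {
        mean(abs(q_emp - q_hat))
      } else {
        mean((q_emp - q_hat)^2)
      }
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  list(mean = mean(fold_errors),
       se = stats::sd(fold_errors) / sqrt(n_folds),
       fold_errors = fold_errors)
}

# deterministic size-stratified fold assignment: order studies by total
# deaths and deal them round-robin
deal_folds <- function(sizes, n_folds) {
  folds <- integer(length(sizes))
  folds[order(sizes, decreasing = TRUE)] <-
    rep_len(seq_len(n_folds), length(sizes))
  folds
}

#' Run cross-validation over the penalty grid
#'
#' @inheritParams cv_error
#' @return Data.frame with one row per lambda: `lambda`, `mean_error`, `se`.
#' @export
cv_grid <- function(studies, matrices, taxonomy, config,
                    sigma_bound = config$sigma_bound_high) {
  res <- lapply(config$lambda_grid, function(lam) {
    cv <- cv_error(studies, matrices, taxonomy, lam, config, sigma_bound)
    data.frame(lambda = lam, mean_error = cv$mean, se = cv$se)
  })
  do.call(rbind, res)
}

#' Select the penalty with the one-standard-error rule
#'
#' When cross-validation does not identify a clearly best penalty, more
#' penalisation is favoured to avoid overfitting: the selected lambda is the
#' LARGEST one whose mean error is within one standard error (of the
#' minimizing lambda's error) of the minimum.
#'
#' @param cv_results Data.frame with columns `lambda`, `mean_error`, `se`,
#'   sorted by ascending lambda.
#' @param multiplier Multiplier on the SE threshold (1 = one-SE rule; 0
#'   picks the plain minimiser, breaking ties upward).
#' @return The selected lambda (scalar).
#' @export
select_penalty <- function(cv_results, multiplier = 1) {
  if (is.null(cv_results) || nrow(cv_results) == 0L) {
    stop("empty cross-validation grid")
  }
  stopifnot(!is.unsorted(cv_results$lambda, strictly = TRUE))
  i_min <- which.min(cv_results$mean_error)
  threshold <- cv_results$mean_error[i_min] +
    multiplier * cv_results$se[i_min]
  max(cv_results$lambda[cv_results$mean_error <= threshold])
}
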