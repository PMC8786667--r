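#' Linear predictor of the multinomial-logit model
#'
#' For each cause `c` other than the base cause, the log odds relative to
#' the base are `eta[c] = x . beta[c, ] + u_s[c]`; the base cause's entry is
#' fixed at zero.
#'
#' @param beta Coefficient matrix, causes x (1 + covariates); the base-cause
#'   row must be zero. Column 1 multiplies the intercept slot of `x`.
#' @param u_s Random-effect vector for the study (length = number of causes,
#'   base entry zero); use zeros for a unit with no random effect.
#' @param x Covariate vector including the leading intercept slot (1).
#' @return Numeric vector of per-cause log odds.
#' @export
linear_predictor <- function(beta, u_s, x) {
  if (any(!is.finite(x))) stop("non-finite covariates in linear predictor")
  stopifnot(ncol(beta) == length(x), nrow(beta) == length(u_s))
  as.numeric(beta %*% x) + u_s
}

#' Cause fractions from log odds
#'
#' The inverse multinomial-logit link: `p[c] = exp(eta[c]) / sum(exp(eta))`,
#' computed with max-subtraction so large log odds cannot overflow.
#'
#' @param eta Numeric vector of per-cause log odds.
#' @return Probability vector summing to 1.
#' @export
softmax_fractions <- function(eta) {
  stopifnot(all(is.finite(eta)))
  e <- exp(eta - max(eta))
  e / sum(e)
}

#' Log likelihood of the misclassification multinomial model
#'
#' Sums, over studies, the multinomial log pmf of the reported-category
#' counts given probabilities `G_s p_s`, where `p_s` are the true-cause
#' fractions implied by `params` for study `s`. Includes the multinomial
#' normalising constant. A reported category with zero probability but a
#' positive count yields `-Inf` with a warning.
#'
#' @param params List with elements `beta` (causes x (1+K), base row zero)
#'   and `u` (studies x causes matrix of random effects, base column zero).
#' @param studies List of `study_dataset` objects.
#' @param matrices List of `misclass_matrix`, one per study.
#' @return Scalar log likelihood.
#' @export
log_likelihood <- function(params, studies, matrices) {
  if (length(studies) != length(matrices)) {
    stop("need exactly one misclassification matrix per study")
  }
  total <- 0
  for (s in seq_along(studies)) {
    st <- studies[[s]]
    G <- matrices[[s]]$G
    x <- c(1, unname(st$covariates))
    u_s <- if (is.null(params$u)) rep(0, nrow(params$beta)) else params$u[s, ]
    p <- softmax_fractions(linear_predictor(params$beta, u_s, x))
    q <- aggregate_probs(G, p)
    y <- as.numeric(st$deaths)
    if (any(y > 0 & q <= 0)) {
      warning("zero reported-category probability with non-zero count ",
              "(study ", st$study_id, ")")
      return(-Inf)
    }
    keep <- y > 0
    total <- total + lgamma(sum(y) + 1) - sum(lgamma(y + 1)) +
      sum(y[keep] * log(q[keep]))
  }
  total
}

#' Log prior density of the model parameters
#'
#' Laplace(0, 1/lambda) shrinkage on non-intercept coefficients (the
#' Bayesian LASSO), a wide normal on intercepts, Normal(0, sigma) on study
#' random effects, and a uniform prior on sigma over (0, sigma_bound].
#'
#' @param params List with `beta`, `u`, and `sigma`.
#' @param lambda Positive LASSO penalty.
#' @param sigma_bound Upper bound for the random-effect SD (0.14 for
#'   high-mortality models by default).
#' @param intercept_sd Prior SD on intercepts.
#' @param base Row index of the base cause in `beta` (excluded from all
#'   terms).
#' @return Scalar log prior density; `-Inf` if sigma is outside its bound.
#' @export
log_prior <- function(params, lambda, sigma_bound = 0.14,
                      intercept_sd = 10, base = NULL) {
  beta <- params$beta
  sigma <- params$sigma
  if (is.null(sigma) || sigma <= 0 || sigma > sigma_bound) return(-Inf)
  rows <- seq_len(nrow(beta))
  if (!is.null(base)) rows <- setdiff(rows, base)
  slopes <- beta[rows, -1, drop = FALSE]
  ints <- beta[rows, 1]
  lp <- sum(log(lambda / 2) - lambda * abs(slopes)) +
    sum(stats::dnorm(ints, 0, intercept_sd, log = TRUE)) -
    log(sigma_bound)   # uniform density on (0, sigma_bound]
  if (!is.null(params$u)) {
    u <- params$u
    ucols <- seq_len(ncol(u))
    if (!is.null(base)) ucols <- setdiff(ucols, base)
    lp <- lp + sum(stats::dnorm(u[, ucols], 0, sigma, log = TRUE))
  }
  lp
}

build_model_data <- function(studies, matrices, taxonomy) {
  stopifnot(length(studies) == length(matrices), length(studies) >= 1)
  causes <- taxonomy$causes
  cov_names <- names(studies[[1L]]$covariates)
  X <- t(vapply(studies, function(s) {
    if (!identical(names(s$covariates), cov_names)) {
      stop("covariate names differ across studies (study ", s$study_id, ")")
    }
    c(1, unname(s$covariates))
  }, numeric(length(cov_names) + 1L)))
  counts <- vector("list", length(studies))
  gidx <- vector("list", length(studies))
  for (s in seq_along(studies)) {
    G <- matrices[[s]]$G
    if (!identical(colnames(G), causes)) {
      stop("misclassification matrix columns must follow the taxonomy ",
           "cause order (study ", studies[[s]]$study_id, ")")
    }
    if (!identical(rownames(G), studies[[s]]$reported_causes)) {
      stop("matrix rows must match the study's reported categories (study ",
           studies[[s]]$study_id, ")")
    }
    counts[[s]] <- as.integer(studies[[s]]$deaths)
    gidx[[s]] <- apply(G, 2L, function(col) which(col == 1L))
  }
  list(X = X, counts = counts, gidx = gidx, cov_names = cov_names)
}

#' Sample the posterior of the multinomial LASSO model
#'
#' Runs an adaptive random-walk Metropolis-within-Gibbs sampler over the
#' penalised coefficients, the study random effects, and the bounded
#' random-effect SD. Chains are initialised at beta = 0, u = 0,
#' sigma = bound/2 with per-chain jitter; step sizes adapt during burn-in
#' only. Draws are reproducible given the seed.
#'
#' @param studies List of `study_dataset` objects.
#' @param matrices List of `misclass_matrix`, one per study, columns in
#'   taxonomy cause order.
#' @param taxonomy A `cause_taxonomy`; its base cause fixes the reference
#'   contrast.
#' @param config A `pipeline_config` (chains, iterations, burn-in, seed,
#'   intercept prior SD, retry limit).
#' @param lambda Positive LASSO penalty for this fit.
#' @param sigma_bound Random-effect SD bound; defaults to the config's
#'   high-mortality bound. Use `config$sigma_bound_low` for low-mortality
#'   fits.
#' @return An object of class `u5cod_fit` holding per-chain draw matrices
#'   (iterations x parameters), parameter names, acceptance rates, and fit
#'   metadata.
#' @export
sample_posterior <- function(studies, matrices, taxonomy, config, lambda,
                             sigma_bound = config$sigma_bound_high) {
  stopifnot(lambda > 0, config$chains >= 1)
  md <- build_model_data(studies, matrices, taxonomy)
  C <- n_causes(taxonomy)
  K1 <- ncol(md$X)
  S <- length(studies)
  base <- base_index(taxonomy)
  causes <- taxonomy$causes
  free_causes <- causes[-base]
  param_names <- c(
    paste0("beta[", rep(free_causes, each = K1), ",",
           rep(c("(Intercept)", md$cov_names), times = C - 1L), "]"),
    paste0("u[", rep(seq_len(S), each = C - 1L), ",",
           rep(free_causes, times = S), "]"),
    "sigma")

  chains <- vector("list", config$chains)
  accept <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + 1000L * (ch - 1L))
    for (attempt in seq_len(config$init_retries + 1L)) {
      beta0 <- matrix(0, C, K1)
      beta0[-base, ] <- stats::rnorm((C - 1L) * K1, 0, 0.1)
      u0 <- matrix(0, S, C)
      u0[, -base] <- stats::rnorm(S * (C - 1L), 0, sigma_bound / 10)
      sigma0 <- stats::runif(1, sigma_bound / 4, sigma_bound * 3 / 4)
      lp0 <- log_likelihood(list(beta = beta0, u = u0), studies, matrices) +
        log_prior(list(beta = beta0, u = u0, sigma = sigma0), lambda,
                  sigma_bound, config$intercept_sd, base)
      if (is.finite(lp0)) break
      if (attempt > config$init_retries) {
        stop("posterior non-finite at initialisation after ",
             config$init_retries, " retries")
      }
    }
    res <- .run_mcmc(md$counts, md$gidx, md$X, base, lambda, sigma_bound,
                     config$intercept_sd, config$iterations, config$burnin,
                     beta0, u0, sigma0, 50L)
    colnames(res$draws) <- param_names
    chains[[ch]] <- res$draws
    accept[[ch]] <- stats::setNames(as.numeric(res$accept), param_names)
  }
  structure(
    list(chains = chains, param_names = param_names, taxonomy = taxonomy,
         cov_names = md$cov_names,
         study_ids = vapply(studies, `[[`, "", "study_id"),
         representative =
           vapply(studies, `[[`, TRUE, "nationally_representative"),
         lambda = lambda, sigma_bound = sigma_bound, accept = accept,
         iterations = config$iterations, burnin = config$burnin),
    class = "u5cod_fit"
  )
}

#' @export
print.u5cod_fit <- function(x, ...) {
  cat("Multinomial LASSO fit (", x$taxonomy$age_group, ", base cause ",
      x$taxonomy$base_cause, ")\n", sep = "")
  cat("  lambda = ", x$lambda, ", sigma bound = ", x$sigma_bound, "\n",
      sep = "")
  cat("  ", length(x$chains), " chains x ", nrow(x$chains[[1L]]),
      " kept draws, ", length(x$param_names), " parameters\n", sep = "")
  cat("  max Gelman-Rubin: ",
      round(max(gelman_rubin(x), na.rm = TRUE), 4), "\n", sep = "")
  invisible(x)
}

#' All draws of a fit stacked across chains
#' @param fit A `u5cod_fit`.
#' @return Matrix (total draws x parameters).
#' @export
fit_draws <- function(fit) do.call(rbind, fit$chains)

#' Posterior draws of the coefficient matrix
#'
#' @param fit A `u5cod_fit`.
#' @return Array (draws x causes x (1+K)) with the base-cause slice zero.
#' @export
beta_draws <- function(fit) {
  d <- fit_draws(fit)
  C <- n_causes(fit$taxonomy)
  K1 <- length(fit$cov_names) + 1L
  base <- base_index(fit$taxonomy)
  arr <- array(0, dim = c(nrow(d), C, K1),
               dimnames = list(NULL, fit$taxonomy$causes,
                               c("(Intercept)", fit$cov_names)))
  free <- setdiff(seq_len(C), base)
  cols <- grep("^beta\\[", fit$param_names)
  # draw columns are ordered cause-major, covariate-minor
  for (i in seq_along(free)) {
    idx <- cols[((i - 1L) * K1 + 1L):(i * K1)]
    arr[, free[i], ] <- d[, idx]
  }
  arr
}

#' Posterior draws of a study's random-effect vector
#'
#' @param fit A `u5cod_fit`.
#' @param study_id Identifier of a fitted study.
#' @return Matrix (draws x causes), base column zero.
#' @export
u_draws <- function(fit, study_id) {
  s <- match(study_id, fit$study_ids)
  if (is.na(s)) stop("study ", study_id, " was not in the fit")
  d <- fit_draws(fit)
  C <- n_causes(fit$taxonomy)
  base <- base_index(fit$taxonomy)
  out <- matrix(0, nrow(d), C,
                dimnames = list(NULL, fit$taxonomy$causes))
  free <- setdiff(seq_len(C), base)
  cols <- grep(paste0("^u\\[", s, ","), fit$param_names)
  out[, free] <- d[, cols]
  out
}

#' Posterior draws of the random-effect SD
#' @param fit A `u5cod_fit`.
#' @return Numeric vector of sigma draws.
#' @export
sigma_draws <- function(fit) fit_draws(fit)[, "sigma"]

#' Gelman-Rubin potential scale reduction factor
#'
#' Computed per parameter from between- and within-chain variances of the
#' kept draws. Parameters with zero variance in every chain (e.g. pinned by
#' the prior) return 1 by convention.
#'
#' @param x A `u5cod_fit` or a list of draw matrices (iterations x
#'   parameters) of equal dimensions, one per chain.
#' @return Named numeric vector of PSRF values.
#' @export
gelman_rubin <- function(x) {
  chains <- if (inherits(x, "u5cod_fit")) x$chains else x
  if (!is.list(chains) || length(chains) < 2L) {
    stop("Gelman-Rubin diagnostics need at least 2 chains")
  }
  n <- unique(vapply(chains, nrow, 1L))
  if (length(n) != 1L) stop("chains must have equal lengths")
  m <- length(chains)
  means <- vapply(chains, colMeans, numeric(ncol(chains[[1L]])))
  vars <- vapply(chains, function(ch) apply(ch, 2L, stats::var),
                 numeric(ncol(chains[[1L]])))
  if (ncol(chains[[1L]]) == 1L) {
    means <- matrix(means, nrow = 1L)
    vars <- matrix(vars, nrow = 1L)
  }
  W <- rowMeans(vars)
  B_over_n <- apply(means, 1L, stats::var)   # B/n
  var_plus <- (n - 1) / n * W + B_over_n
  rhat <- sqrt(var_plus / W)
  rhat[W == 0] <- 1   # degenerate chains: converged by convention
  stats::setNames(rhat, colnames(chains[[1L]]))
}

#' Serialize posterior draws to a columnar text file
#'
#' Long format: `parameter`, `chain`, `iteration`, `value`.
#'
#' @param fit A `u5cod_fit`.
#' @param path File path (CSV).
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  rows <- lapply(seq_along(fit$chains), function(ch) {
    m <- fit$chains[[ch]]
    data.frame(parameter = rep(colnames(m), each = nrow(m)),
               chain = ch,
               iteration = rep(seq_len(nrow(m)), times = ncol(m)),
               value = as.numeric(m),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a convergence diagnostics report
#'
#' Per-parameter Gelman-Rubin statistics and mean acceptance rates as CSV.
#'
#' @param fit A `u5cod_fit`.
#' @param path File path (CSV).
#' @return The report data.frame, invisibly.
#' @export
write_diagnostics <- function(fit, path) {
  gr <- gelman_rubin(fit)
  acc <- Reduce(`+`, fit$accept) / length(fit$accept)
  rpt <- data.frame(parameter = names(gr), gelman_rubin = as.numeric(gr),
                    mean_acceptance = as.numeric(acc[names(gr)]),
                    stringsAsFactors = FALSE)
  utils::write.csv(rpt, path, row.names = FALSE)
  invisible(rpt)
}
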