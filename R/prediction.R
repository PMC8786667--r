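#' Classify a country-year into a mortality stratum
#'
#' Strata are defined on the all-cause mortality rate (deaths per 1000
#' livebirths): below the low threshold the low-mortality model applies, at
#' or above the high threshold the high-mortality model applies, and in the
#' moderate band the two models are averaged with a weight that moves
#' linearly in the rate (10-20 for neonates, 25-35 for children aged 1-59
#' months, by default).
#'
#' @param rate Non-negative rate(s).
#' @param age_group `"neonatal"` or `"child_1to59m"`.
#' @param thresholds Named list of `c(low, high)` per age group (defaults
#'   from [pipeline_config()]).
#' @return Data.frame with `rate`, `stratum` (`"low"`, `"moderate"`,
#'   `"high"`), and `weight_high` in `[0, 1]`.
#' @examples
#' classify_stratum(c(5, 15, 25), "neonatal")
#' @export
classify_stratum <- function(rate, age_group = c("neonatal", "child_1to59m"),
                             thresholds = NULL) {
  age_group <- match.arg(age_group)
  if (is.null(thresholds)) thresholds <- pipeline_config()$thresholds
  th <- thresholds[[age_group]]
  if (any(rate < 0)) stop("mortality rate must be non-negative")
  L <- th[["low"]]
  H <- th[["high"]]
  w <- pmin(pmax((rate - L) / (H - L), 0), 1)
  stratum <- ifelse(rate < L, "low", ifelse(rate >= H, "high", "moderate"))
  data.frame(rate = rate, stratum = stratum, weight_high = w,
             stringsAsFactors = FALSE)
}

#' Predict cause-fraction draws for a country-year
#'
#' Applies each posterior draw of the coefficients to the country-year's
#' covariates. Random effects: for a country with a nationally
#' representative study in the fit, that study's random-effect draws are
#' used; otherwise the point prediction uses u = 0, and (for uncertainty
#' only) u can be drawn from Normal(0, sigma draw).
#'
#' @param fit A `u5cod_fit`.
#' @param x Covariate vector without intercept, aligned with the fitted
#'   covariate names.
#' @param study_effect Either `NULL` (u = 0), the `study_id` of a
#'   nationally representative fitted study, or a draws x causes matrix of
#'   random-effect draws.
#' @param sample_u If `TRUE` and `study_effect` is `NULL`, draw u from
#'   Normal(0, sigma) per draw so random-effect variability enters the
#'   uncertainty.
#' @return Matrix (draws x causes) of cause-fraction draws, rows summing
#'   to 1.
#' @export
predict_fractions <- function(fit, x, study_effect = NULL,
                              sample_u = FALSE) {
  if (length(x) != length(fit$cov_names)) {
    stop("covariate length mismatch: got ", length(x), ", fitted model has ",
         length(fit$cov_names))
  }
  barr <- beta_draws(fit)
  n <- dim(barr)[1L]
  C <- dim(barr)[2L]
  xi <- c(1, unname(x))
  eta <- matrix(0, n, C)
  for (k in seq_along(xi)) eta <- eta + barr[, , k] * xi[k]
  if (is.character(study_effect)) {
    eta <- eta + u_draws(fit, study_effect)
  } else if (is.matrix(study_effect)) {
    stopifnot(nrow(study_effect) == n, ncol(study_effect) == C)
    eta <- eta + study_effect
  } else if (sample_u) {
    base <- base_index(fit$taxonomy)
    sig <- sigma_draws(fit)
    un <- matrix(stats::rnorm(n * C, 0, rep(sig, C)), n, C)
    un[, base] <- 0
    eta <- eta + un
  }
  p <- t(apply(eta, 1L, softmax_fractions))
  colnames(p) <- fit$taxonomy$causes
  p
}

#' Average low- and high-mortality model fractions
#'
#' In the moderate stratum the two fitted models are combined
#' proportionately to the mortality rate: per draw,
#' `f = w f_high + (1 - w) f_low`, then renormalized. Cause lists are
#' harmonized by name first; a cause absent from one model (neonatal
#' diarrhoea in the low-mortality model, fixed at zero) enters with
#' fraction 0.
#'
#' @param frac_low,frac_high Draws x causes matrices with column names.
#' @param weight_high Averaging weight in `[0, 1]` (1 = high model only).
#' @return Draws x causes matrix over the union cause list.
#' @export
average_models <- function(frac_low, frac_high, weight_high) {
  stopifnot(weight_high >= 0, weight_high <= 1,
            nrow(frac_low) == nrow(frac_high))
  if (is.null(colnames(frac_low)) || is.null(colnames(frac_high))) {
    stop("fraction draws must have cause names")
  }
  causes <- union(colnames(frac_high), colnames(frac_low))
  pad <- function(m) {
    out <- matrix(0, nrow(m), length(causes),
                  dimnames = list(NULL, causes))
    out[, colnames(m)] <- m
    out
  }
  lo <- pad(frac_low)
  hi <- pad(frac_high)
  f <- weight_high * hi + (1 - weight_high) * lo
  f / rowSums(f)
}

#' Complete a vital-registration empirical fraction series
#'
#' Countries with high-functioning vital registration use their reported
#' cause fractions directly. Years without data are filled by linear
#' interpolation per cause between reporting years, renormalized to sum to
#' one; years beyond the reporting span carry the nearest reported
#' distribution forward (or backward).
#'
#' @param vr_series Data.frame with column `year` and one column per cause
#'   holding that year's empirical fractions; only reporting years appear.
#' @param target_years Integer vector of years to fill.
#' @return Data.frame with `year` and per-cause fraction columns for every
#'   target year, each row summing to 1.
#' @export
vr_empirical_fractions <- function(vr_series, target_years) {
  stopifnot("year" %in% names(vr_series))
  if (nrow(vr_series) == 0L) stop("no vital-registration reporting years")
  causes <- setdiff(names(vr_series), "year")
  vr_series <- vr_series[order(vr_series$year), , drop = FALSE]
  out <- data.frame(year = as.integer(target_years))
  for (cz in causes) {
    if (nrow(vr_series) == 1L) {
      out[[cz]] <- rep(vr_series[[cz]], length(target_years))
    } else {
      out[[cz]] <- stats::approx(vr_series$year, vr_series[[cz]],
                                 xout = target_years, rule = 2)$y
    }
  }
  tot <- rowSums(out[causes])
  if (any(tot <= 0)) stop("interpolated fractions sum to zero")
  out[causes] <- out[causes] / tot
  out
}
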