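#' Run the fixed-order post-processing chain for one draw
#'
#' The order of operations is fixed and documented: envelope squeezing
#' against the exogenous single-cause series, pooled-cause splits
#' (sepsis/meningitis for neonates, perinatal for children), tuberculosis
#' carve-out, vaccine adjustment, crisis attribution. Deaths are conserved
#' at every step.
#'
#' @param fractions Named modelled cause fractions summing to 1.
#' @param envelope_deaths All-cause deaths for the country-year.
#' @param exogenous Named non-negative vector of exogenous cause deaths;
#'   `tb_pulmonary` and `tb_extrapulmonary` entries feed the TB carve-out,
#'   the rest are squeezed.
#' @param meningitis_ratio Optional proportion for
#'   [split_neonatal_sepsis()] (applies when a `sepsis_meningitis` cause is
#'   present).
#' @param preterm_share Optional proportion for [split_perinatal()]
#'   (applies when a `perinatal` cause is present).
#' @param vaccine Optional list of vaccine adjustments, each
#'   `list(cause =, coverage =, ve_paf =, cov_ref =)`.
#' @param crisis Optional `list(deaths =, type =)` crisis attribution.
#' @param cap_share Cap share for [squeeze_exogenous()].
#' @return Named vector of cause deaths summing to `envelope_deaths`.
#' @export
postprocess_chain <- function(fractions, envelope_deaths, exogenous = NULL,
                              meningitis_ratio = NULL, preterm_share = NULL,
                              vaccine = NULL, crisis = NULL,
                              cap_share = 0.9) {
  tb_causes <- c("tb_pulmonary", "tb_extrapulmonary")
  tb <- exogenous[intersect(names(exogenous), tb_causes)]
  squeeze <- exogenous[setdiff(names(exogenous), tb_causes)]
  deaths <- squeeze_exogenous(envelope_deaths, fractions,
                              squeeze, cap_share)
  if (!is.null(meningitis_ratio) && "sepsis_meningitis" %in% names(deaths)) {
    sp <- split_neonatal_sepsis(deaths[["sepsis_meningitis"]],
                                meningitis_ratio)
    deaths <- deaths[setdiff(names(deaths), "sepsis_meningitis")]
    deaths <- c(deaths, sepsis = sp$sepsis, meningitis = sp$meningitis)
  }
  if (!is.null(preterm_share) && "perinatal" %in% names(deaths)) {
    sp <- split_perinatal(deaths[["perinatal"]], preterm_share)
    deaths <- deaths[setdiff(names(deaths), "perinatal")]
    deaths <- c(deaths, preterm = sp$preterm, intrapartum = sp$intrapartum)
  }
  if (length(tb)) {
    lri <- if ("lower_respiratory_infections" %in% names(deaths))
      deaths[["lower_respiratory_infections"]] else 0
    oth <- if ("other" %in% names(deaths)) deaths[["other"]] else 0
    adj <- allocate_tb(lri,
                       oth,
                       if ("tb_pulmonary" %in% names(tb))
                         tb[["tb_pulmonary"]] else 0,
                       if ("tb_extrapulmonary" %in% names(tb))
                         tb[["tb_extrapulmonary"]] else 0)
    if ("lower_respiratory_infections" %in% names(deaths))
      deaths[["lower_respiratory_infections"]] <- adj$lri
    if ("other" %in% names(deaths)) deaths[["other"]] <- adj$other_communicable
    deaths <- c(deaths, tb = adj$tb)
  }
  if (!is.null(vaccine)) {
    for (v in vaccine) {
      if (v$cause %in% names(deaths)) {
        deaths <- vaccine_adjust(deaths, v$cause, v$coverage, v$ve_paf,
                                 if (is.null(v$cov_ref)) 0 else v$cov_ref)
      }
    }
  }
  if (!is.null(crisis) && crisis$deaths > 0) {
    frac_now <- deaths / sum(deaths)
    deaths <- allocate_crisis(sum(deaths), frac_now, crisis$deaths,
                              crisis$type)
  }
  deaths
}

#' Monte-Carlo propagation of all uncertainty sources
#'
#' For each draw: a cause-fraction vector is taken from the posterior draws
#' (resampled with replacement if more draws are requested than available),
#' an envelope draw is sampled lognormally around the point envelope, each
#' exogenous cause is sampled lognormally around its point estimate, and
#' the full post-processing chain is run. The result is the per-cause death
#' draws from which uncertainty ranges are computed.
#'
#' @param fraction_draws Draws x causes matrix of modelled fractions.
#' @param envelope_deaths Point all-cause deaths.
#' @param envelope_sd_log SD on the log scale for envelope draws (0 =
#'   degenerate).
#' @param exogenous Named vector of point exogenous deaths.
#' @param exogenous_sd_log SD(s) on the log scale for exogenous draws
#'   (recycled).
#' @param n_draws Number of Monte-Carlo draws (positive).
#' @param seed Integer seed.
#' @param ... Further arguments passed to [postprocess_chain()].
#' @return Matrix (n_draws x causes) of death draws.
#' @export
propagate_draws <- function(fraction_draws, envelope_deaths,
                            envelope_sd_log = 0, exogenous = NULL,
                            exogenous_sd_log = 0, n_draws, seed, ...) {
  if (n_draws <= 0) stop("n_draws must be positive")
  set.seed(seed)
  idx <- if (n_draws <= nrow(fraction_draws)) {
    seq_len(n_draws)
  } else {
    sample.int(nrow(fraction_draws), n_draws, replace = TRUE)
  }
  env_draws <- if (envelope_sd_log > 0) {
    envelope_deaths * stats::rlnorm(n_draws, 0, envelope_sd_log)
  } else {
    rep(envelope_deaths, n_draws)
  }
  exo_draws <- NULL
  if (!is.null(exogenous) && length(exogenous)) {
    sds <- rep_len(exogenous_sd_log, length(exogenous))
    exo_draws <- vapply(seq_along(exogenous), function(j) {
      if (sds[j] > 0) {
        exogenous[[j]] * stats::rlnorm(n_draws, 0, sds[j])
      } else {
        rep(exogenous[[j]], n_draws)
      }
    }, numeric(n_draws))
    if (n_draws == 1L) exo_draws <- matrix(exo_draws, nrow = 1L)
    colnames(exo_draws) <- names(exogenous)
  }
  out <- NULL
  for (d in seq_len(n_draws)) {
    exo_d <- if (is.null(exo_draws)) NULL else
      stats::setNames(exo_draws[d, ], colnames(exo_draws))
    res <- postprocess_chain(fraction_draws[idx[d], ], env_draws[d],
                             exogenous = exo_d, ...)
    if (is.null(out)) {
      out <- matrix(0, n_draws, length(res),
                    dimnames = list(NULL, names(res)))
    }
    out[d, ] <- res
  }
  out
}

#' 95% uncertainty range of Monte-Carlo draws
#'
#' The uncertainty range is the 2.5th-97.5th centile of the draws, computed
#' with linear interpolation between order statistics (R's default type-7
#' quantile convention).
#'
#' @param draws Numeric vector of at least 40 draws.
#' @return Named vector `c(lower =, upper =)`.
#' @export
uncertainty_range <- function(draws) {
  if (length(draws) < 40L) {
    stop("at least 40 draws are needed for a 2.5-97.5 centile range")
  }
  q <- stats::quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  c(lower = q[1L], upper = q[2L])
}

#' Aggregate country draws to regions
#'
#' Country death draws are summed per draw within region (so correlations
#' are carried into the regional uncertainty) and a `global` element sums
#' all countries. Percentiles should be computed after this summation, not
#' by summing country ranges.
#'
#' @param country_draws Named list (by ISO3 country) of draws x causes
#'   matrices with identical dimensions.
#' @param lookup Data.frame with columns `country`, `region` mapping every
#'   country to exactly one region; defaults to the bundled UNICEF-style
#'   table.
#' @return Named list (by region, plus `"global"`) of draws x causes
#'   matrices.
#' @export
aggregate_region_draws <- function(country_draws, lookup = region_lookup()) {
  stopifnot(length(country_draws) >= 1L)
  regions <- lookup$region[match(names(country_draws), lookup$country)]
  if (anyNA(regions)) {
    stop("country not mapped to a region: ",
         paste(names(country_draws)[is.na(regions)], collapse = ", "))
  }
  out <- lapply(split(seq_along(country_draws), regions), function(ix) {
    Reduce(`+`, country_draws[ix])
  })
  out$global <- Reduce(`+`, country_draws)
  out
}

#' Aggregate a long estimates table to regions
#'
#' Point aggregation of the estimates table: regional cause deaths are the
#' sums of member-country deaths, regional fractions are cause deaths over
#' total deaths. For uncertainty ranges use [aggregate_region_draws()] on
#' the draws instead.
#'
#' @param estimates Long estimates data.frame (see [write_estimates()]).
#' @param lookup Country-to-region lookup data.frame.
#' @return Data.frame with region, year, age_group, cause, deaths and
#'   fraction.
#' @export
aggregate_region <- function(estimates, lookup = region_lookup()) {
  region <- lookup$region[match(estimates$country, lookup$country)]
  if (anyNA(region)) {
    stop("country not mapped to a region: ",
         paste(unique(estimates$country[is.na(region)]), collapse = ", "))
  }
  agg <- stats::aggregate(
    deaths ~ region + year + age_group + cause,
    data = transform(estimates, region = region), FUN = sum)
  tot <- stats::aggregate(deaths ~ region + year + age_group, data = agg,
                          FUN = sum)
  names(tot)[names(tot) == "deaths"] <- "total_deaths"
  agg <- merge(agg, tot, by = c("region", "year", "age_group"))
  agg$fraction <- agg$deaths / agg$total_deaths
  agg$total_deaths <- NULL
  agg[order(agg$region, agg$year, agg$cause), ]
}

#' Cause-specific mortality rate per 1000 livebirths
#'
#' @param deaths Cause-specific deaths.
#' @param livebirths Livebirths (positive).
#' @return Rate per 1000 livebirths.
#' @export
cause_rate <- function(deaths, livebirths) {
  if (any(livebirths <= 0)) stop("livebirths must be positive")
  deaths / livebirths * 1000
}

#' Average annual rate of reduction
#'
#' The log-linear decline rate between two years, in percent per year:
#' `ARR = 100 ln(rate_t1 / rate_t2) / (t2 - t1)`. Positive when mortality
#' falls, negative when it rises.
#'
#' @param rate_t1,rate_t2 Positive rates at the two years.
#' @param t1,t2 Calendar years with `t2 > t1`.
#' @return ARR in percent per year.
#' @examples
#' annual_rate_reduction(10, 5, 2000, 2015)  # ~4.62% per year
#' @export
annual_rate_reduction <- function(rate_t1, rate_t2, t1, t2) {
  if (any(rate_t1 <= 0) || any(rate_t2 <= 0)) {
    stop("ARR is undefined for zero or negative rates; report undefined ",
         "instead")
  }
  if (t2 <= t1) stop("t2 must be after t1")
  100 * log(rate_t1 / rate_t2) / (t2 - t1)
}

#' Required versus projected cause rates at an SDG-style target
#'
#' Assuming cause fractions are unchanged when the target all-cause rate is
#' reached, the required cause rate at the target year is the current
#' fraction times the target all-cause rate; the projected rate continues
#' the current ARR: `projected = current * exp(-ARR/100 * years)`. Causes
#' whose projection exceeds the requirement are flagged as off track.
#'
#' @param current_rates Named vector of current cause-specific rates.
#' @param arr Named vector of ARRs (percent per year), aligned with
#'   `current_rates`.
#' @param current_year,target_year Calendar years.
#' @param target_all_cause Target all-cause rate (positive).
#' @return Data.frame with cause, current, required, projected, and
#'   `off_track`.
#' @export
sdg_projection <- function(current_rates, arr, current_year = 2019L,
                           target_year = 2030L, target_all_cause) {
  stopifnot(target_all_cause > 0, target_year > current_year)
  fractions <- current_rates / sum(current_rates)
  years <- target_year - current_year
  required <- fractions * target_all_cause
  projected <- current_rates * exp(-arr / 100 * years)
  data.frame(cause = names(current_rates),
             current = as.numeric(current_rates),
             required = as.numeric(required),
             projected = as.numeric(projected),
             off_track = as.numeric(projected) > as.numeric(required),
             stringsAsFactors = FALSE)
}

#' Summarise death draws into an estimates row block
#'
#' Computes point estimates (draw means), fractions, rates, and 95%
#' uncertainty ranges for one country-year.
#'
#' @param death_draws Draws x causes matrix.
#' @param country,year,age_group Identifiers for the rows.
#' @param livebirths Livebirths for the rate denominator.
#' @return Data.frame in the long estimates schema.
#' @export
summarise_country_year <- function(death_draws, country, year, age_group,
                                   livebirths) {
  pt <- colMeans(death_draws)
  ur <- apply(death_draws, 2L, uncertainty_range)
  data.frame(country = country, year = year, age_group = age_group,
             cause = colnames(death_draws),
             fraction = as.numeric(pt / sum(pt)),
             deaths = as.numeric(pt),
             rate = cause_rate(as.numeric(pt), livebirths),
             lower = as.numeric(ur["lower", ]),
             upper = as.numeric(ur["upper", ]),
             stringsAsFactors = FALSE, row.names = NULL)
}
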