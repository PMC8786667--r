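#' Apply modelled cause fractions to a mortality envelope
#'
#' Cause-specific deaths are the fractions times the all-cause envelope
#' deaths for the country-year-age group; the cause total equals the
#' envelope by construction.
#'
#' @param fractions Named numeric vector summing to 1.
#' @param envelope_deaths All-cause deaths (scalar, >= 0).
#' @return Named vector of deaths per cause.
#' @examples
#' apply_envelope(c(a = 0.5, b = 0.3, c = 0.2), 1000)
#' @export
apply_envelope <- function(fractions, envelope_deaths) {
  if (abs(sum(fractions) - 1) > 1e-6) {
    stop("cause fractions must sum to 1 (got ", sum(fractions), ")")
  }
  stopifnot(envelope_deaths >= 0)
  fractions * envelope_deaths
}

#' Squeeze exogenous single-cause series into the envelope
#'
#' Single-cause death counts estimated outside the model (measles, HIV,
#' tetanus, reported malaria, ...) are taken at face value, capped at a
#' configurable share of the envelope (pro-rata rescale beyond it), and the
#' remaining envelope is distributed over the modelled causes by their
#' fractions. The total is conserved exactly.
#'
#' @param envelope_deaths All-cause deaths (scalar).
#' @param fractions Named modelled cause fractions summing to 1; the
#'   exogenous causes must not appear among them.
#' @param exogenous Named non-negative vector of exogenous cause deaths.
#' @param cap_share Maximum share of the envelope available to the exogenous
#'   block (default 0.9).
#' @return Named vector over modelled + exogenous causes, summing to
#'   `envelope_deaths`.
#' @examples
#' squeeze_exogenous(1000, c(a = 0.5, b = 0.5), c(measles = 100, hiv = 50))
#' @export
squeeze_exogenous <- function(envelope_deaths, fractions, exogenous,
                              cap_share = 0.9) {
  if (length(exogenous) == 0L) {
    return(apply_envelope(fractions, envelope_deaths))
  }
  if (any(exogenous < 0)) stop("negative exogenous deaths")
  if (length(bad <- intersect(names(exogenous), names(fractions)))) {
    stop("exogenous causes overlap modelled causes: ",
         paste(bad, collapse = ", "))
  }
  if (abs(sum(fractions) - 1) > 1e-6) {
    stop("modelled fractions must sum to 1")
  }
  E <- sum(exogenous)
  cap <- cap_share * envelope_deaths
  if (E > cap) {
    exogenous <- exogenous * cap / E   # pro-rata rescale to the cap
    E <- cap
  }
  c(fractions * (envelope_deaths - E), exogenous)
}

#' Split pooled sepsis/meningitis deaths (neonates)
#'
#' Neonatal meningitis is estimated as an externally supplied proportion of
#' the pooled sepsis-or-meningitis deaths; the split conserves the total.
#'
#' @param sepsis_meningitis_deaths Pooled deaths (scalar or vector).
#' @param meningitis_ratio Proportion in `[0, 1]` allocated to meningitis.
#' @return List with `sepsis` and `meningitis`.
#' @export
split_neonatal_sepsis <- function(sepsis_meningitis_deaths,
                                  meningitis_ratio) {
  if (any(meningitis_ratio < 0 | meningitis_ratio > 1)) {
    stop("meningitis ratio must lie in [0, 1]")
  }
  list(sepsis = (1 - meningitis_ratio) * sepsis_meningitis_deaths,
       meningitis = meningitis_ratio * sepsis_meningitis_deaths)
}

#' Split pooled perinatal deaths (children 1-59 months)
#'
#' Perinatal-cause deaths are divided into preterm birth complications and
#' intrapartum-related events using externally supplied relative
#' proportions. With no external table an equal split is used, with a
#' warning.
#'
#' @param perinatal_deaths Pooled deaths (scalar or vector).
#' @param preterm_share Proportion in `[0, 1]` allocated to preterm birth
#'   complications; `NULL` means no external estimate is available.
#' @return List with `preterm` and `intrapartum`.
#' @export
split_perinatal <- function(perinatal_deaths, preterm_share = NULL) {
  if (is.null(preterm_share)) {
    warning("no external perinatal split supplied; using an equal split")
    preterm_share <- 0.5
  }
  if (any(preterm_share < 0 | preterm_share > 1)) {
    stop("preterm share must lie in [0, 1]")
  }
  list(preterm = preterm_share * perinatal_deaths,
       intrapartum = (1 - preterm_share) * perinatal_deaths)
}

#' Carve tuberculosis deaths out of modelled causes
#'
#' Pulmonary tuberculosis deaths are taken as a fraction of lower
#' respiratory infection deaths; extrapulmonary tuberculosis deaths as a
#' fraction of the other-communicable block, with any excess (extrapulmonary
#' TB can be under-recognised) reassigned as a fraction of lower respiratory
#' infections. No category is driven below zero: remaining excess is
#' truncated with a warning. Totals are conserved (TB gains what the source
#' categories lose).
#'
#' @param lri_deaths Lower respiratory infection deaths.
#' @param other_communicable_deaths Other-communicable deaths.
#' @param tb_pulmonary,tb_extrapulmonary Exogenously estimated TB deaths.
#' @return List with adjusted `lri`, `other_communicable`, and total `tb`.
#' @export
allocate_tb <- function(lri_deaths, other_communicable_deaths,
                        tb_pulmonary, tb_extrapulmonary) {
  stopifnot(lri_deaths >= 0, other_communicable_deaths >= 0,
            tb_pulmonary >= 0, tb_extrapulmonary >= 0)
  # extrapulmonary from other-communicable, excess falls through to LRI
  tb_e_from_other <- min(tb_extrapulmonary, other_communicable_deaths)
  excess <- tb_extrapulmonary - tb_e_from_other
  lri_demand <- tb_pulmonary + excess
  tb_from_lri <- min(lri_demand, lri_deaths)
  if (lri_demand > lri_deaths) {
    warning("tuberculosis deaths exceed available source categories; ",
            "truncated by ", signif(lri_demand - lri_deaths, 4))
  }
  list(lri = lri_deaths - tb_from_lri,
       other_communicable = other_communicable_deaths - tb_e_from_other,
       tb = tb_from_lri + tb_e_from_other)
}

#' Adjust cause deaths for vaccine scale-up
#'
#' Study data predate full Hib/PCV/rotavirus rollout, so deaths from the
#' targeted causes (lower respiratory infections and meningitis for
#' Hib/PCV; diarrhoea for rotavirus) are scaled by
#' `(1 - cov * VE * PAF) / (1 - cov_ref * VE * PAF)`, where `cov` is
#' current coverage, `VE * PAF` the vaccine efficacy times the attributable
#' fraction, and `cov_ref` coverage in the study era (0 by default). Freed
#' deaths are reallocated pro rata to the remaining causes so the envelope
#' is conserved.
#'
#' @param deaths Named vector of cause deaths.
#' @param cause Cause to adjust (must name an element of `deaths`).
#' @param coverage Current vaccine coverage in `[0, 1]`.
#' @param ve_paf Vaccine efficacy times population attributable fraction.
#' @param cov_ref Reference (study-era) coverage.
#' @return Named vector of adjusted deaths with the same total.
#' @export
vaccine_adjust <- function(deaths, cause, coverage, ve_paf, cov_ref = 0) {
  stopifnot(cause %in% names(deaths), coverage >= 0, coverage <= 1,
            cov_ref >= 0, cov_ref <= 1)
  factor <- (1 - coverage * ve_paf) / (1 - cov_ref * ve_paf)
  if (factor <= 0 || factor > 1) {
    stop("vaccine adjustment factor outside (0, 1]: ", signif(factor, 4))
  }
  freed <- deaths[[cause]] * (1 - factor)
  out <- deaths
  out[[cause]] <- deaths[[cause]] * factor
  others <- setdiff(names(deaths), cause)
  tot_others <- sum(deaths[others])
  if (freed > 0 && tot_others > 0) {
    out[others] <- deaths[others] + freed * deaths[others] / tot_others
  } else if (freed > 0) {
    out[[cause]] <- out[[cause]] + freed   # nowhere to move the deaths
  }
  out
}

#' Attribute crisis deaths to causes
#'
#' Crisis deaths (isolated events under UN-IGME criteria) are removed from
#' the distributable envelope and attributed by the nature of the crisis:
#' natural disasters to injury, conflict-related malnutrition to the other
#' (group 1) category, congenital epidemics (Zika) to congenital
#' abnormalities, or pro rata over all causes. The non-crisis remainder is
#' distributed by the modelled fractions; totals are conserved.
#'
#' @param envelope_deaths All-cause deaths for the year.
#' @param fractions Named modelled fractions summing to 1.
#' @param crisis_deaths Crisis deaths (<= envelope).
#' @param crisis_type One of `"natural_disaster"`, `"conflict_malnutrition"`,
#'   `"epidemic_congenital"`, `"pro_rata"`.
#' @return Named vector of cause deaths summing to `envelope_deaths`.
#' @export
allocate_crisis <- function(envelope_deaths, fractions, crisis_deaths,
                            crisis_type = c("natural_disaster",
                                            "conflict_malnutrition",
                                            "epidemic_congenital",
                                            "pro_rata")) {
  crisis_type <- match.arg(crisis_type)
  if (crisis_deaths > envelope_deaths) {
    stop("crisis deaths (", crisis_deaths, ") exceed the envelope (",
         envelope_deaths, ")")
  }
  stopifnot(crisis_deaths >= 0)
  out <- apply_envelope(fractions, envelope_deaths - crisis_deaths)
  target <- switch(crisis_type,
                   natural_disaster = "injury",
                   conflict_malnutrition = "other",
                   epidemic_congenital = "congenital",
                   pro_rata = NA_character_)
  if (is.na(target)) {
    out <- out + fractions * crisis_deaths
  } else {
    if (!target %in% names(out)) {
      stop("crisis target cause '", target, "' not among the causes")
    }
    out[[target]] <- out[[target]] + crisis_deaths
  }
  out
}

#' Validate a crisis event record
#'
#' Crises are events isolated to fewer than 5 years with more than ten
#' under-5 deaths.
#'
#' @param country ISO3 code.
#' @param years Inclusive integer span of the event.
#' @param age_group Age group label.
#' @param crisis_deaths Death count (> 10).
#' @param crisis_type See [allocate_crisis()].
#' @return A validated list of class `crisis_event`.
#' @export
crisis_event <- function(country, years, age_group, crisis_deaths,
                         crisis_type = c("natural_disaster",
                                         "conflict_malnutrition",
                                         "epidemic_congenital",
                                         "pro_rata")) {
  crisis_type <- match.arg(crisis_type)
  check_iso3(country)
  span <- max(years) - min(years) + 1L
  if (span >= 5L) stop("crisis events must span fewer than 5 years")
  if (crisis_deaths <= 10) stop("crisis events must involve more than ",
                                "ten deaths")
  structure(list(country = country, years = as.integer(range(years)),
                 age_group = age_group, crisis_deaths = crisis_deaths,
                 crisis_type = crisis_type),
            class = "crisis_event")
}
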