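#' Construct a study dataset
#'
#' One study's (or vital-registration country-year's) reported-cause death
#' counts with its metadata and covariates. Reported categories need not
#' coincide with the taxonomy's true causes: studies that did not report a
#' cause are handled through the misclassification (aggregation) matrix.
#'
#' @param study_id Study identifier.
#' @param country ISO3 country code (3 upper-case characters).
#' @param midyear Calendar midyear of data collection (integer; a study
#'   spanning years is keyed by its midyear rounded down).
#' @param age_group `"neonatal"` or `"child_1to59m"`.
#' @param deaths Named non-negative integer vector: death counts per reported
#'   category, names are the reported categories in order.
#' @param covariates Named finite numeric vector of study-level covariates
#'   (without intercept).
#' @param nationally_representative Logical flag.
#' @param source_type `"va_study"` or `"vr_country_year"`.
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(study_id, country, midyear,
                          age_group = c("neonatal", "child_1to59m"),
                          deaths, covariates = numeric(0),
                          nationally_representative = FALSE,
                          source_type = c("va_study", "vr_country_year")) {
  age_group <- match.arg(age_group)
  source_type <- match.arg(source_type)
  check_iso3(country)
  stopifnot(is.numeric(deaths), !is.null(names(deaths)))
  if (any(deaths < 0)) stop("negative death counts in study ", study_id)
  if (any(deaths != round(deaths))) {
    stop("death counts must be integers in study ", study_id)
  }
  if (anyDuplicated(names(deaths))) {
    stop("duplicated reported cause in study ", study_id, ": ",
         paste(unique(names(deaths)[duplicated(names(deaths))]),
               collapse = ", "))
  }
  if (length(covariates) && (is.null(names(covariates)) ||
                             any(!is.finite(covariates)))) {
    stop("covariates must be a named finite numeric vector (study ",
         study_id, ")")
  }
  structure(
    list(study_id = as.character(study_id),
         country = country,
         midyear = as.integer(midyear),
         age_group = age_group,
         reported_causes = names(deaths),
         deaths = deaths,
         total_deaths = as.integer(round(sum(deaths))),
         covariates = covariates,
         nationally_representative = isTRUE(nationally_representative),
         source_type = source_type),
    class = "study_dataset"
  )
}

check_iso3 <- function(country) {
  if (!is.character(country) || length(country) != 1L ||
      !grepl("^[A-Z0-9]{3}$", country)) {
    stop("unknown country code: ", paste(country, collapse = ","),
         " (expected a 3-character ISO3-style code)")
  }
  invisible(country)
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("Study ", x$study_id, " (", x$country, ", ", x$midyear, ", ",
      x$age_group, ", ", x$source_type, ")\n", sep = "")
  cat("  ", x$total_deaths, " deaths over ", length(x$reported_causes),
      " reported categories",
      if (x$nationally_representative) "; nationally representative" else "",
      "\n", sep = "")
  invisible(x)
}
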