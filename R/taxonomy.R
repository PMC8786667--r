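#' Cause taxonomies for under-5 mortality estimation
#'
#' A cause taxonomy is the ordered list of "true" causes modelled for an age
#' group, together with one designated reference (base) cause whose
#' multinomial-logit contrast is fixed at zero. The neonatal list covers ages
#' 0-27 days; the child list covers 1-59 months, where preterm birth
#' complications and intrapartum-related events are pooled as "perinatal"
#' causes and split post hoc.
#'
#' @param age_group `"neonatal"` or `"child_1to59m"`.
#' @param causes Character vector of unique cause names. Defaults to the
#'   standard list for the age group.
#' @param base_cause Reference cause; must be an element of `causes`. Defaults
#'   to the high-burden reference used for the high-mortality model of the age
#'   group (intrapartum for neonates, lower respiratory infections for
#'   children).
#' @return An object of class `cause_taxonomy`.
#' @examples
#' cause_taxonomy("neonatal")
#' cause_taxonomy("child_1to59m", base_cause = "lower_respiratory_infections")
#' @export
cause_taxonomy <- function(age_group = c("neonatal", "child_1to59m"),
                           causes = NULL,
                           base_cause = NULL) {
  age_group <- match.arg(age_group)
  if (is.null(causes)) {
    causes <- default_causes(age_group)
  }
  stopifnot(is.character(causes), length(causes) >= 2L)
  if (anyDuplicated(causes)) {
    stop("cause names must be unique; duplicated: ",
         paste(unique(causes[duplicated(causes)]), collapse = ", "))
  }
  required <- default_causes(age_group)
  missing <- setdiff(required, causes)
  if (length(missing)) {
    stop("taxonomy for age group '", age_group, "' must contain: ",
         paste(missing, collapse = ", "))
  }
  if (is.null(base_cause)) {
    base_cause <- switch(age_group,
                         neonatal = "intrapartum",
                         child_1to59m = "lower_respiratory_infections")
  }
  if (!base_cause %in% causes) {
    stop("base_cause '", base_cause, "' is not in the cause list")
  }
  structure(
    list(age_group = age_group, causes = causes, base_cause = base_cause),
    class = "cause_taxonomy"
  )
}

default_causes <- function(age_group) {
  switch(age_group,
    neonatal = c("tetanus", "lower_respiratory_infections", "preterm",
                 "intrapartum", "sepsis_meningitis", "congenital",
                 "diarrhoea", "other"),
    child_1to59m = c("lower_respiratory_infections", "diarrhoea",
                     "meningitis", "injury", "malaria", "congenital",
                     "perinatal", "other"),
    stop("unknown age group: ", age_group)
  )
}

#' Reference-cause convention per fitted model
#'
#' Returns the taxonomy with the reference cause enforced for a given
#' mortality stratum model: the neonatal low-mortality model uses preterm
#' birth complications as reference, the neonatal high-mortality model uses
#' intrapartum-related events, and both child models use lower respiratory
#' infections.
#'
#' @param age_group `"neonatal"` or `"child_1to59m"`.
#' @param stratum `"low"` or `"high"` (the moderate band is served by
#'   averaging the two fitted models, not by its own fit).
#' @return A `cause_taxonomy`.
#' @export
model_taxonomy <- function(age_group = c("neonatal", "child_1to59m"),
                           stratum = c("high", "low")) {
  age_group <- match.arg(age_group)
  stratum <- match.arg(stratum)
  base <- if (age_group == "neonatal") {
    if (stratum == "low") "preterm" else "intrapartum"
  } else {
    "lower_respiratory_infections"
  }
  cause_taxonomy(age_group, base_cause = base)
}

#' @export
print.cause_taxonomy <- function(x, ...) {
  cat("Cause taxonomy (", x$age_group, "): ", length(x$causes), " causes\n",
      sep = "")
  cat("  causes: ", paste(x$causes, collapse = ", "), "\n", sep = "")
  cat("  base cause: ", x$base_cause, "\n", sep = "")
  invisible(x)
}

#' Number of causes in a taxonomy
#' @param taxonomy A `cause_taxonomy`.
#' @return Integer count of causes.
#' @export
n_causes <- function(taxonomy) length(taxonomy$causes)

#' Index of the base cause
#' @param taxonomy A `cause_taxonomy`.
#' @return Integer position of the base cause in the cause list.
#' @export
base_index <- function(taxonomy) match(taxonomy$base_cause, taxonomy$causes)
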