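#' Read study datasets from a delimited-text file
#'
#' Expects a UTF-8 comma-separated file with one row per study x reported
#' cause and columns `study_id`, `country`, `midyear`, `age_group`,
#' `reported_cause`, `deaths`, `nationally_representative`, `source_type`,
#' plus any number of covariate columns prefixed `cov_`. Covariates must be
#' constant within a study.
#'
#' Reported categories outside the taxonomy's cause list are allowed; they
#' must be resolved by a cause mapping when the study's misclassification
#' matrix is built (see [build_misclass_matrix()]).
#'
#' @param path File path.
#' @param taxonomy A `cause_taxonomy` used for validation of the age group.
#' @return A list of `study_dataset` objects.
#' @export
read_studies <- function(path, taxonomy) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("study_id", "country", "midyear", "age_group",
              "reported_cause", "deaths")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("study file missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    warning("study file ", path, " has a header but no rows")
    return(list())
  }
  if (any(bad <- df$deaths < 0)) {
    stop("negative death count at row ", which(bad)[1L], " of ", path)
  }
  key <- paste(df$study_id, df$reported_cause, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicated (study_id, reported_cause) row: ",
         d$study_id, " / ", d$reported_cause)
  }
  cov_cols <- grep("^cov_", names(df), value = TRUE)
  lapply(split(df, factor(df$study_id, levels = unique(df$study_id))),
         function(rows) {
    covs <- numeric(0)
    if (length(cov_cols)) {
      covs <- as.numeric(rows[1L, cov_cols])
      names(covs) <- sub("^cov_", "", cov_cols)
      if (nrow(unique(rows[cov_cols])) != 1L) {
        stop("covariates vary within study ", rows$study_id[1L])
      }
    }
    deaths <- stats::setNames(rows$deaths, rows$reported_cause)
    study_dataset(
      study_id = rows$study_id[1L],
      country = rows$country[1L],
      midyear = rows$midyear[1L],
      age_group = rows$age_group[1L],
      deaths = deaths,
      covariates = covs,
      nationally_representative =
        isTRUE(as.logical(rows$nationally_representative[1L])),
      source_type = if ("source_type" %in% names(rows))
        rows$source_type[1L] else "va_study"
    )
  })
}

#' Write study datasets to a delimited-text file
#'
#' Inverse of [read_studies()]: one row per study x reported category.
#'
#' @param studies List of `study_dataset` objects.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_studies <- function(studies, path) {
  rows <- lapply(studies, function(s) {
    df <- data.frame(study_id = s$study_id, country = s$country,
                     midyear = s$midyear, age_group = s$age_group,
                     reported_cause = s$reported_causes,
                     deaths = as.numeric(s$deaths),
                     nationally_representative = s$nationally_representative,
                     source_type = s$source_type,
                     stringsAsFactors = FALSE)
    for (nm in names(s$covariates)) {
      df[[paste0("cov_", nm)]] <- s$covariates[[nm]]
    }
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read all-cause mortality envelopes
#'
#' Columns: `country`, `year`, `age_group`, `deaths`, `livebirths`, and
#' optionally `draw_sd_log` (SD on the log scale used when sampling envelope
#' draws; 0 if absent). The rate per 1000 livebirths is computed, not read.
#'
#' @param path File path.
#' @return A data.frame with one row per country-year-age group and a
#'   computed `rate` column.
#' @export
read_envelopes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("country", "year", "age_group", "deaths", "livebirths")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("envelope file missing columns: ", paste(missing, collapse = ", "))
  }
  if (any(df$livebirths <= 0)) {
    stop("livebirths must be positive (row ",
         which(df$livebirths <= 0)[1L], ")")
  }
  if (any(df$deaths < 0)) {
    stop("envelope deaths must be non-negative (row ",
         which(df$deaths < 0)[1L], ")")
  }
  df$rate <- df$deaths / df$livebirths * 1000
  if (is.null(df$draw_sd_log)) df$draw_sd_log <- 0
  df
}

#' Read exogenous single-cause death series
#'
#' Series estimated outside the multinomial model (measles, HIV, tetanus,
#' reported malaria, pulmonary and extrapulmonary tuberculosis) that are
#' reconciled with the envelope by squeezing. Columns: `country`, `year`,
#' `age_group`, `cause`, `deaths`, optional `draw_sd_log`.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_exogenous <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("country", "year", "age_group", "cause", "deaths")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("exogenous series file missing columns: ",
         paste(missing, collapse = ", "))
  }
  allowed <- c("measles", "hiv", "tetanus", "malaria_reported",
               "tb_pulmonary", "tb_extrapulmonary")
  if (length(bad <- setdiff(unique(df$cause), allowed))) {
    stop("unknown exogenous cause(s): ", paste(bad, collapse = ", "))
  }
  if (any(df$deaths < 0)) stop("exogenous deaths must be non-negative")
  if (is.null(df$draw_sd_log)) df$draw_sd_log <- 0
  df
}

estimate_cols <- c("country", "year", "age_group", "cause", "fraction",
                   "deaths", "rate", "lower", "upper")

#' Write country-cause estimates
#'
#' Long-format table (country, year, age_group, cause, fraction, deaths,
#' rate, lower, upper) written so that numeric values survive a read-back
#' bit for bit.
#'
#' @param estimates A data.frame with the columns above.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  if (nrow(estimates) == 0L) {
    writeLines(paste(estimate_cols, collapse = ","), path)
    return(invisible(path))
  }
  stopifnot(all(estimate_cols %in% names(estimates)))
  out <- estimates[estimate_cols]
  for (nm in c("fraction", "deaths", "rate", "lower", "upper")) {
    out[[nm]] <- sprintf("%.17g", out[[nm]])  # lossless double round-trip
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back country-cause estimates written by [write_estimates()]
#' @param path File path.
#' @return A data.frame in the long estimates schema.
#' @export
read_estimates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(country = "character",
                                       cause = "character"))
  missing <- setdiff(estimate_cols, names(df))
  if (length(missing)) {
    stop("estimates file missing columns: ", paste(missing, collapse = ", "))
  }
  df
}

#' Bundled UNICEF-style region lookup
#'
#' Returns the editable ISO3-to-region lookup table shipped with the package
#' (`inst/extdata/unicef_regions.csv`). Synthetic analyses can pass their own
#' lookup to [aggregate_region()] instead.
#'
#' @return A data.frame with columns `country` and `region`.
#' @export
region_lookup <- function() {
  utils::read.csv(system.file("extdata", "unicef_regions.csv",
                              package = "u5cod"),
                  stringsAsFactors = FALSE)
}
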