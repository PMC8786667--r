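#' Build a study's misclassification (aggregation) matrix
#'
#' The matrix `G` translating the common true-cause list into the categories
#' a study actually reported. It is not estimated: each true cause is
#' assigned to exactly one reported category, so `G` is binary with every
#' column summing to 1. A study reporting all causes gets the identity; a
#' study that pooled causes gets rows with several 1s.
#'
#' @param taxonomy A `cause_taxonomy` (columns of `G` follow its cause
#'   order).
#' @param reported_causes Character vector of the study's reported categories
#'   (rows of `G`, in order).
#' @param mapping Named character vector: for every true cause, the reported
#'   category it falls into. If `NULL`, the default convention applies:
#'   causes present in `reported_causes` map to themselves and every other
#'   true cause maps to the study's `"other"` category; if the study has no
#'   `"other"` category the construction fails rather than guessing.
#' @param study_id Optional identifier attached to the matrix.
#' @return An object of class `misclass_matrix`: a list with the binary
#'   matrix `G` (reported categories x true causes) and `study_id`.
#' @examples
#' tax <- cause_taxonomy("child_1to59m")
#' # a study pooling meningitis into "other":
#' rep_causes <- setdiff(tax$causes, "meningitis")
#' G <- build_misclass_matrix(tax, rep_causes)
#' colSums(G$G)  # every true cause maps somewhere: all 1
#' @export
build_misclass_matrix <- function(taxonomy, reported_causes, mapping = NULL,
                                  study_id = NA_character_) {
  causes <- taxonomy$causes
  if (anyDuplicated(reported_causes)) {
    stop("reported categories must be unique")
  }
  if (is.null(mapping)) {
    mapping <- default_cause_mapping(taxonomy, reported_causes)
  }
  unmapped <- setdiff(causes, names(mapping))
  if (length(unmapped)) {
    stop("true cause(s) not mapped to a reported category: ",
         paste(unmapped, collapse = ", "))
  }
  bad <- setdiff(names(mapping), causes)
  if (length(bad)) {
    stop("mapping names unknown true cause(s): ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(unname(mapping[causes]), reported_causes)
  if (length(bad)) {
    stop("mapping targets category not reported by the study: ",
         paste(unique(bad), collapse = ", "))
  }
  unused <- setdiff(reported_causes, mapping[causes])
  if (length(unused)) {
    stop("reported category with no mapped cause: ",
         paste(unused, collapse = ", "))
  }
  G <- matrix(0L, nrow = length(reported_causes), ncol = length(causes),
              dimnames = list(reported_causes, causes))
  G[cbind(match(mapping[causes], reported_causes), seq_along(causes))] <- 1L
  structure(list(study_id = study_id, G = G), class = "misclass_matrix")
}

#' Default cause mapping for a study
#'
#' Causes the study reported map to themselves; unreported causes fall into
#' the study's residual `"other"` category.
#'
#' @inheritParams build_misclass_matrix
#' @return Named character vector (true cause -> reported category).
#' @export
default_cause_mapping <- function(taxonomy, reported_causes) {
  causes <- taxonomy$causes
  mapping <- ifelse(causes %in% reported_causes, causes, NA_character_)
  names(mapping) <- causes
  if (anyNA(mapping)) {
    if (!"other" %in% reported_causes) {
      stop("study reports no 'other' category; cannot map unreported ",
           "cause(s): ", paste(causes[is.na(mapping)], collapse = ", "),
           " -- supply an explicit mapping")
    }
    mapping[is.na(mapping)] <- "other"
  }
  mapping
}

#' Read per-study cause mappings from CSV
#'
#' Columns: `study_id`, `true_cause`, `reported_category`.
#'
#' @param path File path.
#' @return Named list (by study_id) of named character vectors suitable for
#'   `build_misclass_matrix(mapping = )`.
#' @export
read_cause_mappings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("study_id", "true_cause", "reported_category")
                %in% names(df)))
  lapply(split(df, df$study_id), function(rows) {
    stats::setNames(rows$reported_category, rows$true_cause)
  })
}

#' Aggregate true-cause probabilities to reported categories
#'
#' Computes `q = G p`. Because every column of `G` sums to one, probability
#' mass is conserved: `sum(q) == sum(p)`.
#'
#' @param G A `misclass_matrix` (or a bare binary matrix).
#' @param p Probability vector over the true causes (length `ncol(G)`).
#' @return Probability vector over the reported categories.
#' @export
aggregate_probs <- function(G, p) {
  M <- if (inherits(G, "misclass_matrix")) G$G else G
  if (length(p) != ncol(M)) {
    stop("dimension mismatch: ", length(p), " probabilities for ",
         ncol(M), " true causes")
  }
  as.numeric(M %*% p)
}

#' @export
print.misclass_matrix <- function(x, ...) {
  cat("Misclassification matrix",
      if (!is.na(x$study_id)) paste0(" (study ", x$study_id, ")"),
      ": ", nrow(x$G), " reported categories x ", ncol(x$G),
      " true causes\n", sep = "")
  print(x$G)
  invisible(x)
}

#' Misclassification matrices for a list of studies
#'
#' Applies [build_misclass_matrix()] to each study, using an explicit mapping
#' when one is supplied for the study and the default residual-category
#' convention otherwise.
#'
#' @param studies List of `study_dataset` objects.
#' @param taxonomy A `cause_taxonomy`.
#' @param mappings Optional named list of per-study mappings (see
#'   [read_cause_mappings()]).
#' @return List of `misclass_matrix`, parallel to `studies`.
#' @export
study_matrices <- function(studies, taxonomy, mappings = NULL) {
  lapply(studies, function(s) {
    build_misclass_matrix(taxonomy, s$reported_causes,
                          mapping = mappings[[s$study_id]],
                          study_id = s$study_id)
  })
}
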