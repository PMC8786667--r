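# Shared fixtures built in code.

# Small taxonomies for likelihood/aggregation unit tests. Built directly
# (the exported constructor enforces the full age-group cause lists, which
# toy cases deliberately avoid).
toy_taxonomy <- function(causes = c("A", "B", "C"), base = causes[1L],
                         age_group = "child_1to59m") {
  structure(list(age_group = age_group, causes = causes, base_cause = base),
            class = "cause_taxonomy")
}

toy_study <- function(deaths, study_id = "s1", country = "S01",
                      midyear = 2010L, covariates = numeric(0),
                      representative = FALSE,
                      age_group = "child_1to59m") {
  study_dataset(study_id = study_id, country = country, midyear = midyear,
                age_group = age_group, deaths = deaths,
                covariates = covariates,
                nationally_representative = representative)
}

# config with short chains for fits inside unit tests
fast_config <- function(...) {
  pipeline_config(chains = 2L, iterations = 400L, burnin = 400L, ...)
}

# enumerate all count vectors of length k summing to n
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  out <- NULL
  for (i in 0:n) {
    rest <- compositions(n - i, k - 1L)
    out <- rbind(out, cbind(i, rest))
  }
  unname(out)
}
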