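# Minimal valid evidence rows for unit tests; defaults are a significant
# protective estimate so single fields can be perturbed per test.
make_estimate <- function(outcome_id = "breast_cancer",
                          exposure_category = "total_dairy",
                          srre = 0.85, ci_lower = 0.76, ci_upper = 0.95,
                          n_studies = 10L, first_author = "Dong",
                          pub_year = 2011L, ...) {
  tibble::tibble(
    outcome_id = outcome_id,
    exposure_category = exposure_category,
    comparison = "high vs. low",
    srre = srre,
    ci_lower = ci_lower,
    ci_upper = ci_upper,
    n_studies = n_studies,
    i_squared = NA_real_,
    p_heterogeneity = NA_real_,
    first_author = first_author,
    pub_year = pub_year,
    funding_source = NA_character_,
    ...
  )
}

write_evidence_csv <- function(evidence, path = withr::local_tempfile(fileext = ".csv",
                                                                      .local_envir = parent.frame())) {
  readr::write_csv(evidence, path, na = "")
  path
}

canonical_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(run_analysis(burden_config()))
    }
    cache
  }
})
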