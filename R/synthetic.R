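#' Generate a synthetic meta-analytic evidence base
#'
#' Emulates the statistical shape of a protective-only SRRE registry: true
#' relative risks drawn log-normally and truncated to (0, 1), symmetric (on
#' the log scale) 95% confidence intervals of configurable width, and
#' plausible study counts and metadata. The generating RR for each outcome is
#' returned alongside, so downstream stages can be checked against known
#' truth. Synthetic SRREs are drawn directly; meta-analytic pooling itself is
#' not simulated.
#'
#' @param n_outcomes Number of synthetic (outcome, exposure) estimates.
#' @param true_rr_log_mean,true_rr_log_sd Mean and sd of `log(RR)` before
#'   truncation to RR in (0, 1). Defaults centre on the moderate protective
#'   effects typical of dairy meta-analyses (RR around 0.85).
#' @param ci_halfwidth_log_sd Standard error of `log(RR)` used to build the
#'   95% CI; `0` collapses the CI onto the point estimate.
#' @param n_studies_range Integer interval to draw study counts from.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list: `evidence` (a validated evidence tibble) and `truth`
#'   (tibble of `outcome_id`, `true_rr`).
#' @export
generate_evidence <- function(n_outcomes,
                              true_rr_log_mean = log(0.85),
                              true_rr_log_sd = 0.08,
                              ci_halfwidth_log_sd = 0.05,
                              n_studies_range = c(2L, 21L),
                              seed = 1L) {
  stopifnot(n_outcomes >= 1, true_rr_log_sd > 0, ci_halfwidth_log_sd >= 0)
  withr::local_seed(seed)

  # rejection-sample log(RR) < 0 so every SRRE is strictly protective
  log_rr <- numeric(0)
  while (length(log_rr) < n_outcomes) {
    draw <- stats::rnorm(n_outcomes, true_rr_log_mean, true_rr_log_sd)
    log_rr <- c(log_rr, draw[draw < 0])
  }
  log_rr <- log_rr[seq_len(n_outcomes)]
  rr <- exp(log_rr)
  half <- 1.96 * ci_halfwidth_log_sd

  evidence <- tibble::tibble(
    outcome_id = sprintf("synthetic_outcome_%02d", seq_len(n_outcomes)),
    exposure_category = sample(EXPOSURE_CATEGORIES, n_outcomes, replace = TRUE),
    comparison = "high vs. low",
    srre = rr,
    ci_lower = exp(log_rr - half),
    ci_upper = exp(log_rr + half),
    n_studies = sample(seq(n_studies_range[1], n_studies_range[2]),
                       n_outcomes, replace = TRUE),
    i_squared = stats::runif(n_outcomes, 0, 100),
    p_heterogeneity = stats::runif(n_outcomes),
    first_author = sprintf("Synth%02d", seq_len(n_outcomes)),
    pub_year = sample(2010:2021, n_outcomes, replace = TRUE),
    funding_source = NA_character_
  )
  list(
    evidence = validate_evidence(evidence),
    truth = tibble::tibble(outcome_id = evidence$outcome_id, true_rr = rr)
  )
}

#' Generate stratified DALY inputs with a known aggregate
#'
#' Produces a plausible stratified table of raw burden inputs — deaths and
#' standard-loss years for the YLL side, incident cases, disability weights
#' and durations for the YLD side — across sex and age-group strata, plus the
#' cause-level aggregate computed with [aggregate_burden()]. The aggregate
#' equals the brute-force per-stratum sum by construction, which the tests
#' verify independently.
#'
#' @param n_causes Number of synthetic causes (`>= 1`).
#' @param seed Integer seed.
#' @return A list: `strata` (the raw input tibble) and `burden` (cause-level
#'   `yll`, `yld`, `dalys`).
#' @export
generate_daly_inputs <- function(n_causes, seed = 1L) {
  stopifnot(n_causes >= 1)
  withr::local_seed(seed)
  strata <- tidyr::crossing(
    outcome_id = sprintf("synthetic_cause_%02d", seq_len(n_causes)),
    sex = c("female", "male"),
    age_group = c("0-29", "30-59", "60+")
  )
  n <- nrow(strata)
  strata <- dplyr::mutate(
    strata,
    year = 2019L,
    n_deaths = stats::rpois(n, lambda = 2000),
    loss_years = stats::runif(n, 5, 45),
    incident_cases = stats::rpois(n, lambda = 10000),
    disability_weight = stats::runif(n, 0, 1),
    duration_years = stats::runif(n, 0.5, 20)
  )
  list(strata = strata, burden = aggregate_burden(strata))
}

#' Simulate an individual-level cohort with binary exposure
#'
#' The empirical ground for the PARP formula. "Exposure" here is LOW dairy
#' intake — the harmful direction — so the exposed group's risk is the
#' high-intake baseline multiplied by `rr_inverse >= 1`, exactly the
#' population the inverted-SRRE attributable-risk calculation describes.
#' Disease is a single binary (cumulative-incidence) outcome per person.
#'
#' @param n_individuals Cohort size.
#' @param pr_exposed Proportion with low intake, in `[0, 1]`.
#' @param baseline_risk Disease probability in the high-intake (unexposed)
#'   reference group.
#' @param rr_inverse Relative risk for the exposed group, `>= 1`;
#'   `baseline_risk * rr_inverse` must not exceed 1.
#' @param seed Integer seed.
#' @return A tibble with one row per exposure group: `exposed` (logical),
#'   `n`, `cases`.
#' @export
simulate_cohort <- function(n_individuals, pr_exposed, baseline_risk,
                            rr_inverse, seed = 1L) {
  stopifnot(n_individuals >= 1)
  if (is.na(pr_exposed) || pr_exposed < 0 || pr_exposed > 1) {
    db_abort("`pr_exposed` must lie in [0, 1]", "dairyburden_domain_error")
  }
  stopifnot_scalar_prob(baseline_risk, "baseline_risk", open_left = FALSE)
  if (is.na(rr_inverse) || rr_inverse < 1) {
    db_abort("`rr_inverse` must be >= 1 (the exposure is the harmful, low-intake direction)",
             "dairyburden_domain_error")
  }
  if (baseline_risk * rr_inverse > 1) {
    db_abort("`baseline_risk * rr_inverse` must not exceed 1", "dairyburden_domain_error")
  }
  withr::local_seed(seed)
  n_exposed <- stats::rbinom(1, n_individuals, pr_exposed)
  n_unexposed <- n_individuals - n_exposed
  tibble::tibble(
    exposed = c(TRUE, FALSE),
    n = c(n_exposed, n_unexposed),
    cases = c(
      stats::rbinom(1, n_exposed, baseline_risk * rr_inverse),
      stats::rbinom(1, n_unexposed, baseline_risk)
    )
  )
}

#' Empirical population attributable fraction from cohort counts
#'
#' The model-free estimate the PARP formula approximates: the share of
#' observed cases in excess of what the whole cohort would have experienced
#' at the unexposed (high-intake) attack rate,
#' `(observed - N_total * rate_unexposed) / observed`.
#'
#' @param counts A tibble as returned by [simulate_cohort()]: columns
#'   `exposed`, `n`, `cases`.
#' @return A proportion (can be slightly negative by sampling noise under a
#'   null effect).
#' @export
empirical_paf <- function(counts) {
  stopifnot(is.data.frame(counts), all(c("exposed", "n", "cases") %in% names(counts)))
  total_cases <- sum(counts$cases)
  if (total_cases <= 0) {
    db_abort("empirical PAF is undefined with zero cases", "dairyburden_domain_error")
  }
  unexp <- counts[!counts$exposed, ]
  if (sum(unexp$n) == 0) {
    db_abort("empirical PAF requires an unexposed group", "dairyburden_domain_error")
  }
  rate_unexposed <- sum(unexp$cases) / sum(unexp$n)
  expected <- rate_unexposed * sum(counts$n)
  (total_cases - expected) / total_cases
}

#' Delta-method standard error of the empirical PAF
#'
#' Binomial sampling error of [empirical_paf()], treating the unexposed
#' attack rate and the overall attack rate as (approximately independent)
#' binomial proportions and propagating through `1 - p0 / p`.
#'
#' @param counts As in [empirical_paf()].
#' @return Standard error of the empirical PAF.
#' @export
empirical_paf_se <- function(counts) {
  stopifnot(is.data.frame(counts), all(c("exposed", "n", "cases") %in% names(counts)))
  unexp <- counts[!counts$exposed, ]
  n0 <- sum(unexp$n)
  p0 <- sum(unexp$cases) / n0
  n <- sum(counts$n)
  p <- sum(counts$cases) / n
  ratio <- p0 / p
  ratio * sqrt(p0 * (1 - p0) / (n0 * p0^2) + p * (1 - p) / (n * p^2))
}
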