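#' Preventive fraction Pr(1 - RR)
#'
#' Proportion of disease in a population that would be prevented if a
#' fraction `pr` of the population were exposed to a protective factor with
#' relative risk `rr < 1` (high vs. low intake). Defined here only for
#' protective or null estimates; a harmful `rr > 1` is a domain error rather
#' than a negative fraction.
#'
#' @param pr Prevalence of exposure, in `(0, 1]`. Vectorized.
#' @param rr Relative risk, in `(0, 1]`. Vectorized.
#' @return `pr * (1 - rr)`, a proportion in `[0, 1)`.
#' @examples
#' preventive_fraction(0.15, 0.85) # 0.0225
#' @export
preventive_fraction <- function(pr, rr) {
  stopifnot_scalar_prob(pr, "pr")
  if (any(is.na(rr) | rr <= 0 | rr > 1)) {
    db_abort("`rr` must lie in (0, 1]: the preventive fraction is defined only for protective or null estimates",
             "dairyburden_domain_error")
  }
  pr * (1 - rr)
}

#' Invert a relative risk
#'
#' Re-expresses a protective high-vs-low relative risk as the risk of the
#' complementary low-intake exposure: `RR_I = 1 / RR`. This is the harmful
#' direction fed to [parp()].
#'
#' @param rr Relative risk, `> 0`. Vectorized.
#' @return `1 / rr`.
#' @examples
#' invert_rr(0.85) # 1.1764706...
#' @export
invert_rr <- function(rr) {
  if (any(is.na(rr) | rr <= 0)) {
    db_abort("`rr` must be > 0", "dairyburden_domain_error")
  }
  1 / rr
}

#' Population attributable risk proportion (PARP)
#'
#' Levin-style attributable fraction for a harmful exposure with relative
#' risk `rr_inverse >= 1` at prevalence `pr`:
#' `Pr(RR_I - 1) / [1 + Pr(RR_I - 1)]`. In this workflow the exposure is LOW
#' dairy intake, so `rr_inverse` is the inverse of a protective SRRE; values
#' below 1 (low intake appearing protective) are a domain error.
#'
#' @param pr Prevalence of exposure, in `(0, 1]`. Vectorized.
#' @param rr_inverse Relative risk of the harmful exposure, `>= 1`.
#' @return A proportion in `[0, 1)`.
#' @examples
#' parp(0.15, invert_rr(0.85)) # 0.02578797 -> prints as 2.58%
#' @export
parp <- function(pr, rr_inverse) {
  stopifnot_scalar_prob(pr, "pr")
  if (any(is.na(rr_inverse) | rr_inverse < 1)) {
    db_abort("`rr_inverse` must be >= 1 (the inverted estimate must not be protective)",
             "dairyburden_domain_error")
  }
  excess <- pr * (rr_inverse - 1)
  excess / (1 + excess)
}

#' Build the default prevalence grid
#'
#' The conservative range of exposure prevalences used throughout:
#' 15%, 25%, 35% and 50% of the population consuming dairy at the studies'
#' highest intake stratum.
#'
#' @param pr Numeric vector of prevalences in `(0, 1]`, strictly increasing.
#' @return A tibble with columns `pr` and `label` (e.g. `"Pr 15%"`).
#' @export
prevalence_grid <- function(pr = c(0.15, 0.25, 0.35, 0.50)) {
  stopifnot_scalar_prob(pr, "pr")
  if (length(pr) == 0) {
    db_abort("prevalence grid must be non-empty", "dairyburden_domain_error")
  }
  if (is.unsorted(pr, strictly = TRUE)) {
    db_abort("prevalence grid must be strictly increasing", "dairyburden_domain_error")
  }
  tibble::tibble(pr = pr, label = paste0("Pr ", formatC(100 * pr, format = "fg"), "%"))
}

#' Sweep preventive fractions and PARPs over a prevalence grid
#'
#' Expands each protective estimate across every prevalence scenario,
#' computing the preventive fraction `Pr(1 - RR)` and the PARP on the
#' inverted estimate. Full floating precision is kept; rounding happens only
#' in report formatting.
#'
#' @param evidence Evidence rows that passed the significance gate (see
#'   [build_analysis_set()]).
#' @param grid A prevalence grid from [prevalence_grid()], or a bare numeric
#'   vector of prevalences.
#' @return A tibble with one row per (estimate, scenario):
#'   `outcome_id`, `exposure_category`, `pr`, `rr`, `rr_inverse`,
#'   `preventive_fraction`, `parp`.
#' @examples
#' ev <- dairy_evidence()
#' sweep_fractions(ev[ev$outcome_id == "breast_cancer" &
#'                    ev$exposure_category == "total_dairy", ])
#' @export
sweep_fractions <- function(evidence, grid = prevalence_grid()) {
  stopifnot(is.data.frame(evidence))
  if (!is.data.frame(grid)) grid <- prevalence_grid(grid)
  if (nrow(grid) == 0) {
    db_abort("prevalence grid must be non-empty", "dairyburden_domain_error")
  }
  if (nrow(evidence) == 0) {
    return(tibble::tibble(
      outcome_id = character(), exposure_category = character(),
      pr = double(), rr = double(), rr_inverse = double(),
      preventive_fraction = double(), parp = double()
    ))
  }
  if (any(!is_protective_significant(evidence))) {
    db_abort("all estimates must pass the significance gate (ci_upper < 1) before sweeping",
             "dairyburden_domain_error")
  }
  tidyr::crossing(
    evidence[c("outcome_id", "exposure_category", "srre")],
    grid["pr"]
  ) |>
    dplyr::transmute(
      .data$outcome_id, .data$exposure_category, .data$pr,
      rr = .data$srre,
      rr_inverse = invert_rr(.data$srre),
      preventive_fraction = preventive_fraction(.data$pr, .data$srre),
      parp = parp(.data$pr, .data$rr_inverse)
    ) |>
    dplyr::arrange(
      match(.data$exposure_category, EXPOSURE_CATEGORIES),
      .data$outcome_id, .data$pr
    )
}

#' Propagate CI bounds through the fraction formulas
#'
#' Recomputes the preventive fraction and PARP substituting the confidence
#' limits of the SRRE for its point estimate, giving a (conservative,
#' optimistic) pair per scenario. This is an uncertainty illustration the
#' point-estimate tables deliberately omit, and is excluded from
#' golden-table comparisons. When `ci_upper >= 1` the conservative bound is
#' clamped to 0 and flagged rather than raised as an error.
#'
#' @param evidence Evidence rows (need `srre`, `ci_lower`, `ci_upper`).
#' @param grid Prevalence grid as in [sweep_fractions()].
#' @return A tibble with, per (estimate, scenario), the point fractions plus
#'   `pf_conservative`, `pf_optimistic`, `parp_conservative`,
#'   `parp_optimistic`, and `conservative_clamped` (TRUE where the CI upper
#'   bound crossed the null and the conservative bound was set to 0).
#' @export
interval_fractions <- function(evidence, grid = prevalence_grid()) {
  stopifnot(is.data.frame(evidence))
  if (!is.data.frame(grid)) grid <- prevalence_grid(grid)
  if (nrow(grid) == 0) {
    db_abort("prevalence grid must be non-empty", "dairyburden_domain_error")
  }
  tidyr::crossing(
    evidence[c("outcome_id", "exposure_category", "srre", "ci_lower", "ci_upper")],
    grid["pr"]
  ) |>
    dplyr::mutate(
      rr = .data$srre,
      rr_inverse = invert_rr(.data$srre),
      preventive_fraction = preventive_fraction(.data$pr, .data$srre),
      parp = parp(.data$pr, .data$rr_inverse),
      conservative_clamped = .data$ci_upper >= 1,
      pf_conservative = pmax(.data$pr * (1 - .data$ci_upper), 0),
      pf_optimistic = .data$pr * (1 - .data$ci_lower),
      parp_conservative = parp(.data$pr, pmax(1 / .data$ci_upper, 1)),
      parp_optimistic = parp(.data$pr, 1 / .data$ci_lower)
    )
}
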