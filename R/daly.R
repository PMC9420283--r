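#' Years of life lost (YLL)
#'
#' `YLL = N x L`: deaths multiplied by the standard loss function, the
#' remaining life expectancy at the age of death under the highest projected
#' 2050 life table. The loss table is an input, never hard-coded.
#'
#' @param n_deaths Number of deaths, `>= 0`. Vectorized.
#' @param loss_years Standard-loss-function years per death, `>= 0`.
#' @return Person-years of life lost.
#' @export
compute_yll <- function(n_deaths, loss_years) {
  if (any(is.na(n_deaths) | n_deaths < 0) || any(is.na(loss_years) | loss_years < 0)) {
    db_abort("`n_deaths` and `loss_years` must be non-negative", "dairyburden_domain_error")
  }
  n_deaths * loss_years
}

#' Years lived with disability (YLD)
#'
#' `YLD = I x DW x L`: incident cases multiplied by the disability weight
#' (0 = perfect health, 1 = death-equivalent) and the average duration of a
#' case until remission or death.
#'
#' @param incident_cases Incident case count, `>= 0`. Vectorized.
#' @param disability_weight Severity weight in `[0, 1]`.
#' @param duration_years Average case duration in years, `>= 0`.
#' @return Person-years lived with disability.
#' @export
compute_yld <- function(incident_cases, disability_weight, duration_years) {
  if (any(is.na(incident_cases) | incident_cases < 0) ||
      any(is.na(duration_years) | duration_years < 0)) {
    db_abort("`incident_cases` and `duration_years` must be non-negative",
             "dairyburden_domain_error")
  }
  if (any(is.na(disability_weight) | disability_weight < 0 | disability_weight > 1)) {
    db_abort("`disability_weight` must lie in [0, 1]", "dairyburden_domain_error")
  }
  incident_cases * disability_weight * duration_years
}

#' Compose a DALY from its components
#'
#' `DALY = YLL + YLD` for a given cause, sex, age and year. Age-weighting and
#' time-discounting are omitted, matching the WHO Global Health Estimates
#' convention for these aggregates.
#'
#' @param yll,yld Person-years, `>= 0`. Vectorized.
#' @return Person-years.
#' @export
compose_daly <- function(yll, yld) {
  if (any(is.na(yll) | yll < 0) || any(is.na(yld) | yld < 0)) {
    db_abort("YLL and YLD components must be non-negative", "dairyburden_domain_error")
  }
  yll + yld
}

#' Aggregate a stratified YLL/YLD input table to cause-level burden
#'
#' The engine accepts either pre-aggregated cause-level DALY totals (the
#' usual pathway, e.g. WHO GHE aggregates) or a stratified table of raw
#' inputs per (cause, sex, age group, year). This helper collapses the
#' stratified form: per stratum `N x L + I x DW x L`, summed over strata
#' within each cause.
#'
#' @param strata A data frame with columns `outcome_id`, `n_deaths`,
#'   `loss_years`, `incident_cases`, `disability_weight`, `duration_years`,
#'   and optionally `sex`, `age_group`, `year`.
#' @return A tibble with one row per `outcome_id`: `yll`, `yld`, `dalys`.
#' @export
aggregate_burden <- function(strata) {
  needed <- c("outcome_id", "n_deaths", "loss_years", "incident_cases",
              "disability_weight", "duration_years")
  missing <- setdiff(needed, names(strata))
  if (length(missing) > 0) {
    db_abort(sprintf("stratified burden table is missing column(s): %s",
                     paste(missing, collapse = ", ")),
             "dairyburden_schema_error")
  }
  strata |>
    dplyr::mutate(
      .yll = compute_yll(.data$n_deaths, .data$loss_years),
      .yld = compute_yld(.data$incident_cases, .data$disability_weight,
                         .data$duration_years)
    ) |>
    dplyr::group_by(.data$outcome_id) |>
    dplyr::summarise(
      yll = sum(.data$.yll),
      yld = sum(.data$.yld),
      dalys = compose_daly(.data$yll, .data$yld),
      .groups = "drop"
    )
}

#' Read a cause-level DALY table
#'
#' @param path CSV with columns `outcome_id` and `dalys` (person-years).
#' @return A validated tibble.
#' @seealso [us_dalys_2019()] for the packaged US 2019 totals.
#' @export
read_dalys <- function(path) {
  if (!file.exists(path)) {
    db_abort(sprintf("DALY file not found: %s", path), "dairyburden_io_error")
  }
  check_header(path, c("outcome_id", "dalys"))
  df <- readr::read_csv(
    path,
    col_types = readr::cols(outcome_id = readr::col_character(),
                            dalys = readr::col_double()),
    progress = FALSE, show_col_types = FALSE
  )
  if (!all(c("outcome_id", "dalys") %in% names(df))) {
    db_abort("DALY table must have columns outcome_id, dalys", "dairyburden_schema_error")
  }
  if (any(is.na(df$dalys) | df$dalys < 0)) {
    db_abort("DALY totals must be non-negative", "dairyburden_validation_error")
  }
  tibble::as_tibble(df)
}

#' DALYs preventable at a given preventive fraction
#'
#' @param pf Preventive fraction in `[0, 1)`. Vectorized.
#' @param dalys Cause-level DALY total, person-years.
#' @return `pf * dalys`, person-years. Full precision; display rounding (one
#'   decimal, half-up) is applied only by the report writers, to the product
#'   of the unrounded fraction and the total.
#' @export
preventable_dalys <- function(pf, dalys) {
  if (any(is.na(pf) | pf < 0 | pf >= 1)) {
    db_abort("`pf` must lie in [0, 1)", "dairyburden_domain_error")
  }
  if (any(is.na(dalys) | dalys < 0)) {
    db_abort("`dalys` must be non-negative", "dairyburden_domain_error")
  }
  pf * dalys
}

#' DALYs attributable to the low-intake exposure at a given PARP
#'
#' @param parp Population attributable risk proportion in `[0, 1)`.
#' @param dalys Cause-level DALY total, person-years.
#' @return `parp * dalys`, person-years (full precision, as in
#'   [preventable_dalys()]).
#' @export
attributable_dalys <- function(parp, dalys) {
  if (any(is.na(parp) | parp < 0 | parp >= 1)) {
    db_abort("`parp` must lie in [0, 1)", "dairyburden_domain_error")
  }
  if (any(is.na(dalys) | dalys < 0)) {
    db_abort("`dalys` must be non-negative", "dairyburden_domain_error")
  }
  parp * dalys
}

#' Join fraction cells to cause-level burden
#'
#' Multiplies each scenario's preventive fraction and PARP by the matching
#' cause-level DALY total. Fraction rows whose outcome has no burden entry
#' are dropped with a warning (mirroring exclusion of outcomes absent from
#' the burden catalogue).
#'
#' @param fractions Output of [sweep_fractions()].
#' @param dalys A cause-level DALY table (`outcome_id`, `dalys`).
#' @return A tibble adding `dalys`, `preventable_dalys` and
#'   `attributable_dalys` to each fraction row.
#' @export
apply_burden <- function(fractions, dalys) {
  stopifnot(is.data.frame(fractions), is.data.frame(dalys))
  orphan <- setdiff(unique(fractions$outcome_id), dalys$outcome_id)
  if (length(orphan) > 0) {
    rlang::warn(sprintf(
      "dropping outcome(s) with no DALY entry: %s", paste(orphan, collapse = ", ")
    ), class = "dairyburden_missing_burden")
  }
  dplyr::inner_join(fractions, dalys[c("outcome_id", "dalys")], by = "outcome_id") |>
    dplyr::mutate(
      preventable_dalys = preventable_dalys(.data$preventive_fraction, .data$dalys),
      attributable_dalys = attributable_dalys(.data$parp, .data$dalys)
    )
}
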