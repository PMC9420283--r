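#' Packaged registry of dairy-chronic disease SRREs
#'
#' The canonical evidence base: summary relative risk estimates from
#' published meta-analyses of prospective studies of dairy consumption
#' (total dairy, milk, low-fat and high-fat dairy; high vs. low intake)
#' against six chronic disease outcomes, plus two considered prostate-cancer
#' meta-analyses that fail the protective-significance gate and exercise the
#' exclusion path.
#'
#' @return A validated evidence tibble (16 rows).
#' @seealso [build_analysis_set()] to apply the inclusion rules.
#' @export
dairy_evidence <- function() {
  read_evidence(system.file("extdata", "dairy_evidence.csv",
                            package = "dairyburden", mustWork = TRUE))
}

#' Packaged US 2019 cause-level DALY totals
#'
#' WHO Global Health Estimates DALY totals (person-years) for the United
#' States in 2019, for the six outcomes in the packaged evidence registry.
#'
#' @return A tibble with columns `outcome_id` and `dalys`.
#' @export
us_dalys_2019 <- function() {
  read_dalys(system.file("extdata", "us_dalys_2019.csv",
                         package = "dairyburden", mustWork = TRUE))
}

#' Path to the packaged golden fraction/burden tables
#'
#' The published point-estimate tables — preventive fraction and PARP
#' percentages, and preventable/attributable DALYs — for every (outcome,
#' exposure, prevalence) cell of the canonical analysis, used by
#' [verify_against_golden()]. Two cells of the source tables (low-fat dairy /
#' breast cancer at Pr 35%: the 4.80% preventive fraction and its 62,016.0
#' DALY product) are inconsistent with the stated formula `Pr(1 - RR)`
#' (which gives 5.60% and 72,352.0, the values at Pr 30%); they are flagged
#' in the `known_discrepancy` column and reported separately, never treated
#' as formula targets.
#'
#' @return Path to the golden CSV.
#' @export
golden_tables_path <- function() {
  system.file("extdata", "golden_tables.csv",
              package = "dairyburden", mustWork = TRUE)
}
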