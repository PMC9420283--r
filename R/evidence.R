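#' @importFrom rlang .data
NULL

# required columns of an evidence table, in canonical order
EVIDENCE_COLS <- c(
  "outcome_id", "exposure_category", "comparison", "srre",
  "ci_lower", "ci_upper", "n_studies", "i_squared",
  "p_heterogeneity", "first_author", "pub_year", "funding_source"
)

EXPOSURE_CATEGORIES <- c("total_dairy", "milk", "low_fat_dairy", "high_fat_dairy")

#' Read a meta-analytic evidence table
#'
#' Loads a CSV registry of summary relative risk estimates (SRREs), one row
#' per (outcome, exposure category) meta-analysis, and validates every row.
#' Each row is a pooled high-vs-low relative risk with its 95% confidence
#' interval, study count, heterogeneity statistics and source metadata.
#'
#' @param path Path to a UTF-8 CSV with columns `outcome_id`,
#'   `exposure_category`, `comparison`, `srre`, `ci_lower`, `ci_upper`,
#'   `n_studies`, `i_squared`, `p_heterogeneity`, `first_author`,
#'   `pub_year`, `funding_source`. `i_squared`, `p_heterogeneity` and
#'   `funding_source` may be empty.
#' @return A validated evidence tibble with a `provenance` attribute naming
#'   the source file.
#' @seealso [validate_evidence()], [dairy_evidence()] for the packaged
#'   registry, [build_analysis_set()] for inclusion filtering.
#' @export
read_evidence <- function(path) {
  if (!file.exists(path)) {
    db_abort(sprintf("evidence file not found: %s", path), "dairyburden_io_error")
  }
  check_header(path, EVIDENCE_COLS)
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      outcome_id = readr::col_character(),
      exposure_category = readr::col_character(),
      comparison = readr::col_character(),
      srre = readr::col_double(),
      ci_lower = readr::col_double(),
      ci_upper = readr::col_double(),
      n_studies = readr::col_integer(),
      i_squared = readr::col_double(),
      p_heterogeneity = readr::col_double(),
      first_author = readr::col_character(),
      pub_year = readr::col_integer(),
      funding_source = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  out <- validate_evidence(df)
  attr(out, "provenance") <- path
  out
}

#' Validate an evidence table
#'
#' Checks the schema and the per-estimate invariants: `srre > 0`,
#' `ci_lower > 0`, `ci_lower <= srre <= ci_upper`, `n_studies >= 1`,
#' `i_squared` in `[0, 100]` and `p_heterogeneity` in `[0, 1]` where present,
#' and a known exposure category. Violations are reported with row indices.
#'
#' @param evidence A data frame with the columns listed in [read_evidence()].
#' @return The evidence as a tibble, invisibly unchanged, or an error naming
#'   the missing column (schema error) or offending rows (validation error).
#' @export
validate_evidence <- function(evidence) {
  missing <- setdiff(EVIDENCE_COLS, names(evidence))
  if (length(missing) > 0) {
    db_abort(
      sprintf("evidence table is missing required column(s): %s",
              paste(missing, collapse = ", ")),
      "dairyburden_schema_error"
    )
  }
  df <- tibble::as_tibble(evidence)[EVIDENCE_COLS]
  if (nrow(df) == 0) return(df)

  problems <- character(0)
  flag <- function(bad, what) {
    bad <- which(!is.na(bad) & bad)
    if (length(bad) > 0) {
      problems <<- c(problems, sprintf("row %d: %s", bad, what))
    }
  }
  flag(is.na(df$srre) | df$srre <= 0, "srre must be > 0")
  flag(is.na(df$ci_lower) | df$ci_lower <= 0, "ci_lower must be > 0")
  flag(df$ci_lower > df$srre | df$srre > df$ci_upper,
       "confidence interval must bracket srre (ci_lower <= srre <= ci_upper)")
  flag(is.na(df$n_studies) | df$n_studies < 1, "n_studies must be >= 1")
  flag(!is.na(df$i_squared) & (df$i_squared < 0 | df$i_squared > 100),
       "i_squared must be in [0, 100]")
  flag(!is.na(df$p_heterogeneity) &
         (df$p_heterogeneity < 0 | df$p_heterogeneity > 1),
       "p_heterogeneity must be in [0, 1]")
  flag(!df$exposure_category %in% EXPOSURE_CATEGORIES,
       sprintf("exposure_category must be one of %s",
               paste(EXPOSURE_CATEGORIES, collapse = ", ")))
  if (length(problems) > 0) {
    db_abort(
      c("invalid evidence table:", stats::setNames(problems, rep("x", length(problems)))),
      "dairyburden_validation_error"
    )
  }
  df
}

#' Significance gate for protective estimates
#'
#' An estimate enters the preventive-fraction workflow only when its 95%
#' confidence interval lies entirely below the null: `ci_upper < 1`. A CI
#' touching 1.0 (e.g. 1.00-1.78, at best marginally significant) fails, as
#' does any harmful-direction estimate — no consistently significant
#' increased-risk meta-analyses exist in this registry's domain, so such
#' rows are rejected at this gate rather than routed elsewhere.
#'
#' @param evidence An evidence data frame (or any data frame with a
#'   `ci_upper` column).
#' @return Logical vector, one element per row: `TRUE` where the estimate is
#'   statistically significantly protective.
#' @examples
#' ev <- tibble::tibble(ci_upper = c(0.95, 1.22, 1.00))
#' is_protective_significant(ev) # TRUE FALSE FALSE
#' @export
is_protective_significant <- function(evidence) {
  stopifnot(is.data.frame(evidence), "ci_upper" %in% names(evidence))
  !is.na(evidence$ci_upper) & evidence$ci_upper < 1
}

#' Select the primary meta-analysis among competing candidates
#'
#' When several meta-analyses cover the same (outcome, exposure) topic, the
#' most recently published is retained; ties are broken by the larger study
#' count (the measurable proxy for "most analytically comprehensive"), then
#' by first author alphabetically so the choice is deterministic under any
#' input ordering.
#'
#' @param candidates Evidence rows sharing one `(outcome_id,
#'   exposure_category)` pair.
#' @return The single selected row as a tibble.
#' @export
select_primary <- function(candidates) {
  stopifnot(is.data.frame(candidates))
  if (nrow(candidates) == 0) {
    db_abort("select_primary() requires at least one candidate",
             "dairyburden_domain_error")
  }
  key <- unique(candidates[c("outcome_id", "exposure_category")])
  if (nrow(key) > 1) {
    db_abort("candidates must share one (outcome_id, exposure_category) pair",
             "dairyburden_domain_error")
  }
  ord <- order(-candidates$pub_year, -candidates$n_studies, candidates$first_author)
  tibble::as_tibble(candidates[ord[1], , drop = FALSE])
}

#' Apply the two-phase inclusion logic to an evidence base
#'
#' Keeps only estimates that (i) pass the protective-significance gate
#' ([is_protective_significant()]) and (ii) describe an outcome with a
#' cause-level DALY entry, then resolves duplicates per (outcome, exposure)
#' with [select_primary()]. Outcomes lacking burden estimates (e.g.
#' osteoporosis, obesity in the WHO 2019 catalogue) drop out at step (ii).
#'
#' @param evidence A validated evidence table.
#' @param daly_catalog Character vector of `outcome_id` values for which a
#'   DALY total exists, or a data frame with an `outcome_id` column.
#' @return The filtered evidence tibble, ordered by exposure category
#'   (total dairy, milk, low-fat, high-fat) then outcome. An `exclusions`
#'   attribute records each dropped row and the rule that removed it
#'   (`"not_significant"`, `"no_daly_entry"`, or `"superseded"`).
#' @export
build_analysis_set <- function(evidence, daly_catalog) {
  df <- validate_evidence(evidence)
  if (is.data.frame(daly_catalog)) daly_catalog <- daly_catalog$outcome_id
  daly_catalog <- as.character(daly_catalog)

  sig <- is_protective_significant(df)
  in_catalog <- df$outcome_id %in% daly_catalog
  excl <- tibble::tibble(
    outcome_id = character(), exposure_category = character(),
    first_author = character(), pub_year = integer(), rule = character()
  )
  note <- function(rows, rule) {
    if (nrow(rows) == 0) return()
    excl <<- dplyr::bind_rows(
      excl,
      dplyr::mutate(rows[c("outcome_id", "exposure_category", "first_author", "pub_year")],
                    rule = rule)
    )
  }
  note(df[!sig, ], "not_significant")
  note(df[sig & !in_catalog, ], "no_daly_entry")
  kept <- df[sig & in_catalog, ]

  if (nrow(kept) > 0) {
    groups <- split(kept, paste(kept$outcome_id, kept$exposure_category))
    picked <- purrr::map_dfr(groups, select_primary)[EVIDENCE_COLS]
    superseded <- dplyr::anti_join(
      kept, picked,
      by = c("outcome_id", "exposure_category", "first_author", "pub_year", "n_studies")
    )
    note(superseded, "superseded")
    kept <- picked
  }

  out <- dplyr::arrange(
    kept,
    match(.data$exposure_category, EXPOSURE_CATEGORIES),
    .data$outcome_id
  )
  attr(out, "exclusions") <- excl
  out
}
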