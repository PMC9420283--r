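#' Assemble an analysis configuration
#'
#' Bundles everything [run_analysis()] needs: the evidence and burden inputs
#' (paths or in-memory data frames), the prevalence grid, output options,
#' and a seed for the synthetic subcommands (the analysis path itself is
#' fully deterministic and never draws random numbers).
#'
#' @param evidence Path to an evidence CSV (see [read_evidence()]) or a
#'   validated evidence data frame. Defaults to the packaged registry.
#' @param dalys Path to a cause-level DALY CSV (see [read_dalys()]) or a
#'   data frame. Defaults to the packaged US 2019 totals.
#' @param grid Numeric vector of exposure prevalences in `(0, 1]`, strictly
#'   increasing. Default `c(0.15, 0.25, 0.35, 0.50)`.
#' @param output_dir Directory for [write_report()] output.
#' @param report_formats Subset of `"csv"`, `"json"`, `"markdown"`.
#' @param include_intervals Also compute CI-propagated fraction bounds
#'   ([interval_fractions()]); excluded from golden comparisons.
#' @param random_seed Integer seed, used only by synthetic-data commands.
#' @return An object of class `burden_config`.
#' @export
burden_config <- function(evidence = NULL,
                          dalys = NULL,
                          grid = c(0.15, 0.25, 0.35, 0.50),
                          output_dir = ".",
                          report_formats = "csv",
                          include_intervals = FALSE,
                          random_seed = 1L) {
  grid_tbl <- prevalence_grid(grid) # validates (0,1], strictly increasing
  bad <- setdiff(report_formats, c("csv", "json", "markdown"))
  if (length(bad) > 0) {
    db_abort(sprintf("unknown report format(s): %s", paste(bad, collapse = ", ")),
             "dairyburden_domain_error")
  }
  structure(
    list(
      evidence = evidence %||% system.file("extdata", "dairy_evidence.csv",
                                           package = "dairyburden", mustWork = TRUE),
      dalys = dalys %||% system.file("extdata", "us_dalys_2019.csv",
                                     package = "dairyburden", mustWork = TRUE),
      grid = grid_tbl,
      output_dir = output_dir,
      report_formats = report_formats,
      include_intervals = isTRUE(include_intervals),
      random_seed = as.integer(random_seed)
    ),
    class = "burden_config"
  )
}

#' Read an analysis configuration from YAML
#'
#' Recognised keys mirror [burden_config()]: `evidence_path`, `daly_path`,
#' `prevalence_grid`, `output_dir`, `report_formats`, `include_intervals`,
#' `random_seed`. Arguments passed in `...` override file values.
#'
#' @param path YAML file.
#' @param ... Overrides, as in [burden_config()].
#' @return A `burden_config`.
#' @export
read_burden_config <- function(path, ...) {
  if (!file.exists(path)) {
    db_abort(sprintf("config file not found: %s", path), "dairyburden_io_error")
  }
  y <- yaml::read_yaml(path)
  args <- list(
    evidence = y$evidence_path,
    dalys = y$daly_path,
    grid = if (!is.null(y$prevalence_grid)) as.numeric(y$prevalence_grid),
    output_dir = y$output_dir,
    report_formats = y$report_formats,
    include_intervals = y$include_intervals,
    random_seed = y$random_seed
  )
  args <- args[!vapply(args, is.null, logical(1))]
  overrides <- list(...)
  args[names(overrides)] <- overrides
  defaults <- formals(burden_config)
  for (nm in setdiff(names(defaults), c(names(args), "evidence", "dalys"))) {
    args[[nm]] <- eval(defaults[[nm]])
  }
  do.call(burden_config, args)
}

resolve_table <- function(x, reader) {
  if (is.data.frame(x)) return(list(table = x, digest = NA_character_))
  list(table = reader(x), digest = unname(tools::md5sum(x)))
}

#' Run the evidence-to-burden analysis
#'
#' Orchestrates the full pipeline: validate the evidence registry, apply the
#' inclusion rules against the burden catalogue ([build_analysis_set()]),
#' sweep preventive fractions and PARPs over the prevalence grid
#' ([sweep_fractions()]), and apply them to cause-level DALY totals
#' ([apply_burden()]). The result is deterministic: identical inputs and
#' configuration yield byte-identical CSV reports.
#'
#' @param cfg A [burden_config()]. Defaults to the packaged canonical inputs.
#' @return A `burden_report`: a list with tibbles `fractions` (one row per
#'   estimate x scenario) and `burden` (the same cells with preventable and
#'   attributable DALYs), the retained `evidence`, an `exclusions` audit
#'   table (row dropped + triggering rule), optional `intervals`, the `config`
#'   and a `provenance` record (config hash, input digests, timestamp).
#'   Inspect with [tidy()], [glance()], [autoplot()]; persist with
#'   [write_report()]; regression-check with [verify_against_golden()].
#' @export
run_analysis <- function(cfg = burden_config()) {
  stopifnot(inherits(cfg, "burden_config"))
  ev <- resolve_table(cfg$evidence, read_evidence)
  dl <- resolve_table(cfg$dalys, read_dalys)
  evidence <- validate_evidence(ev$table)
  dalys <- dl$table

  analysis_set <- build_analysis_set(evidence, dalys)
  exclusions <- attr(analysis_set, "exclusions")
  if (nrow(exclusions) > 0) {
    for (i in seq_len(nrow(exclusions))) {
      rlang::inform(sprintf(
        "excluded %s / %s (%s %d): %s",
        exclusions$outcome_id[i], exclusions$exposure_category[i],
        exclusions$first_author[i], exclusions$pub_year[i], exclusions$rule[i]
      ), class = "dairyburden_exclusion")
    }
  }
  if (nrow(analysis_set) == 0) {
    db_abort(paste(
      "no estimates survive the inclusion rules;",
      "check that the evidence has protective significant estimates (ci_upper < 1)",
      "and that outcome_id values match the DALY table"
    ), "dairyburden_empty_analysis")
  }

  fractions <- sweep_fractions(analysis_set, cfg$grid)
  burden <- apply_burden(fractions, dalys)
  intervals <- if (cfg$include_intervals) {
    interval_fractions(analysis_set, cfg$grid)
  }

  structure(
    list(
      fractions = fractions,
      burden = burden,
      intervals = intervals,
      evidence = analysis_set,
      exclusions = exclusions,
      config = cfg,
      provenance = list(
        config_hash = rlang::hash(cfg[c("grid", "include_intervals")]),
        evidence_digest = ev$digest,
        daly_digest = dl$digest,
        timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
      )
    ),
    class = "burden_report"
  )
}

#' @export
print.burden_report <- function(x, ...) {
  cat("<burden_report>\n")
  cat(sprintf("  %d estimates x %d prevalence scenarios = %d cells\n",
              nrow(x$evidence), nrow(x$config$grid), nrow(x$burden)))
  cat(sprintf("  exclusions logged: %d\n", nrow(x$exclusions)))
  cat(sprintf("  total preventable DALYs at Pr %g%%: %s\n",
              100 * max(x$burden$pr),
              format_daly(sum(x$burden$preventable_dalys[x$burden$pr == max(x$burden$pr)]))))
  invisible(x)
}

#' Tidy a burden report into one row per analysis cell
#'
#' @param x A `burden_report`.
#' @param ... Unused.
#' @return A tibble with, per (outcome, exposure, prevalence) cell, the
#'   relative risks, fractions and DALY products at full precision.
#' @method tidy burden_report
#' @export
tidy.burden_report <- function(x, ...) {
  tibble::as_tibble(x$burden)
}

#' One-row summary of a burden report
#'
#' @param x A `burden_report`.
#' @param ... Unused.
#' @return A tibble with estimate/scenario/cell counts, the number of logged
#'   exclusions, and total preventable and attributable DALYs at the highest
#'   prevalence scenario.
#' @method glance burden_report
#' @export
glance.burden_report <- function(x, ...) {
  top <- x$burden[x$burden$pr == max(x$burden$pr), ]
  tibble::tibble(
    n_estimates = nrow(x$evidence),
    n_scenarios = nrow(x$config$grid),
    n_cells = nrow(x$burden),
    n_exclusions = nrow(x$exclusions),
    pr_max = max(x$burden$pr),
    preventable_dalys_at_pr_max = sum(top$preventable_dalys),
    attributable_dalys_at_pr_max = sum(top$attributable_dalys)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# display-rounded view used by CSV/markdown writers and the golden harness
report_cells <- function(report) {
  dplyr::mutate(
    report$burden,
    pf_pct = round_half_up(100 * .data$preventive_fraction, 2),
    parp_pct = round_half_up(100 * .data$parp, 2),
    preventable_dalys_rounded = round_half_up(.data$preventable_dalys, 1),
    attributable_dalys_rounded = round_half_up(.data$attributable_dalys, 1)
  )
}

markdown_table <- function(df) {
  cells <- rbind(names(df), rep("---", ncol(df)), as.matrix(df))
  paste0("| ", apply(cells, 1, paste, collapse = " | "), " |")
}

#' Write a burden report to disk
#'
#' One file set per requested format:
#' * `csv`: `fractions.csv` and `burden.csv` with 2-decimal percent and
#'   1-decimal DALY display columns plus full-precision numeric twins;
#' * `json`: the full-precision tables and provenance, round-trippable;
#' * `markdown`: human-readable fraction and burden tables (percent cells to
#'   2 decimals, DALYs to 1 decimal with thousands separators).
#'
#' @param report A `burden_report`.
#' @param output_dir Target directory (created if needed); defaults to the
#'   config's `output_dir`.
#' @param formats Overrides the config's `report_formats`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, output_dir = NULL, formats = NULL) {
  stopifnot(inherits(report, "burden_report"))
  output_dir <- output_dir %||% report$config$output_dir
  formats <- formats %||% report$config$report_formats
  ok <- dir.exists(output_dir) || dir.create(output_dir, recursive = TRUE)
  if (!ok) {
    db_abort(sprintf("cannot create output directory: %s", output_dir),
             "dairyburden_io_error")
  }
  cells <- report_cells(report)
  paths <- character(0)

  if ("csv" %in% formats) {
    fr <- dplyr::transmute(
      cells,
      .data$outcome_id, .data$exposure_category, .data$pr,
      preventive_fraction_pct = formatC(.data$pf_pct, format = "f", digits = 2),
      parp_pct = formatC(.data$parp_pct, format = "f", digits = 2),
      preventive_fraction = .data$preventive_fraction,
      parp = .data$parp
    )
    bu <- dplyr::transmute(
      cells,
      .data$outcome_id, .data$exposure_category, .data$pr, .data$dalys,
      preventable_dalys_display = formatC(.data$preventable_dalys_rounded,
                                          format = "f", digits = 1),
      attributable_dalys_display = formatC(.data$attributable_dalys_rounded,
                                           format = "f", digits = 1),
      preventable_dalys = .data$preventable_dalys,
      attributable_dalys = .data$attributable_dalys
    )
    p1 <- file.path(output_dir, "fractions.csv")
    p2 <- file.path(output_dir, "burden.csv")
    readr::write_csv(fr, p1)
    readr::write_csv(bu, p2)
    paths <- c(paths, p1, p2)
  }

  if ("json" %in% formats) {
    p <- file.path(output_dir, "report.json")
    jsonlite::write_json(
      list(
        fractions = report$fractions,
        burden = report$burden,
        evidence = report$evidence,
        exclusions = report$exclusions,
        grid = report$config$grid,
        provenance = report$provenance
      ),
      p, dataframe = "columns", digits = NA, auto_unbox = TRUE, na = "null"
    )
    paths <- c(paths, p)
  }

  if ("markdown" %in% formats) {
    wide_pf <- cells |>
      dplyr::mutate(label = paste0("Pr ", formatC(100 * .data$pr, format = "fg"), "%"),
                    val = format_pct(.data$preventive_fraction)) |>
      dplyr::select("outcome_id", "exposure_category", "label", "val") |>
      tidyr::pivot_wider(names_from = "label", values_from = "val")
    wide_parp <- cells |>
      dplyr::mutate(label = paste0("Pr ", formatC(100 * .data$pr, format = "fg"), "%"),
                    val = format_pct(.data$parp)) |>
      dplyr::select("outcome_id", "exposure_category", "label", "val") |>
      tidyr::pivot_wider(names_from = "label", values_from = "val")
    wide_prev <- cells |>
      dplyr::mutate(label = paste0("Pr ", formatC(100 * .data$pr, format = "fg"), "%"),
                    val = format_daly(.data$preventable_dalys)) |>
      dplyr::select("outcome_id", "exposure_category", "label", "val") |>
      tidyr::pivot_wider(names_from = "label", values_from = "val")
    wide_attr <- cells |>
      dplyr::mutate(label = paste0("Pr ", formatC(100 * .data$pr, format = "fg"), "%"),
                    val = format_daly(.data$attributable_dalys)) |>
      dplyr::select("outcome_id", "exposure_category", "label", "val") |>
      tidyr::pivot_wider(names_from = "label", values_from = "val")
    lines <- c(
      "## Preventive fractions", markdown_table(wide_pf), "",
      "## Population attributable risk proportions", markdown_table(wide_parp), "",
      "## Preventable DALYs", markdown_table(wide_prev), "",
      "## Attributable DALYs", markdown_table(wide_attr)
    )
    p <- file.path(output_dir, "report.md")
    writeLines(lines, p)
    paths <- c(paths, p)
  }

  invisible(paths)
}

#' Check a report against the golden published tables
#'
#' Recomputes the display-rounded value of every fraction and burden cell
#' and compares it with the golden table. Cells flagged `known_discrepancy`
#' in the golden file — the two published cells inconsistent with the stated
#' formula (low-fat dairy / breast cancer at Pr 35%) — are reported
#' separately, with the formula value alongside the published one, and never
#' counted as failures.
#'
#' @param report A `burden_report` from the canonical fixtures and grid.
#' @param golden Path to a golden CSV (default: the packaged one, see
#'   [golden_tables_path()]).
#' @return A list with tibbles `unexplained` (cells whose rounded value
#'   disagrees with the golden table for no documented reason; empty on a
#'   faithful run) and `known` (the documented discrepancy cells, showing
#'   both the published and the formula value).
#' @export
verify_against_golden <- function(report, golden = golden_tables_path()) {
  stopifnot(inherits(report, "burden_report"))
  check_header(golden, c("outcome_id", "exposure_category", "pr", "pf_pct",
                         "parp_pct", "preventable_dalys", "attributable_dalys"))
  g <- readr::read_csv(
    golden,
    col_types = readr::cols(
      outcome_id = readr::col_character(),
      exposure_category = readr::col_character(),
      pr = readr::col_double(),
      pf_pct = readr::col_double(),
      parp_pct = readr::col_double(),
      preventable_dalys = readr::col_double(),
      attributable_dalys = readr::col_double(),
      known_discrepancy = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  needed <- c("outcome_id", "exposure_category", "pr", "pf_pct", "parp_pct",
              "preventable_dalys", "attributable_dalys")
  if (!all(needed %in% names(g)) || nrow(g) == 0 || anyNA(g[needed])) {
    db_abort("malformed golden table", "dairyburden_schema_error")
  }
  g$known_discrepancy[is.na(g$known_discrepancy)] <- ""

  cells <- report_cells(report)
  joined <- dplyr::inner_join(
    cells, g, by = c("outcome_id", "exposure_category", "pr"),
    suffix = c("_computed", "_golden")
  )
  if (nrow(joined) != nrow(g)) {
    db_abort("report cells do not cover the golden table; run with the canonical fixtures and grid",
             "dairyburden_domain_error")
  }
  long <- dplyr::bind_rows(
    dplyr::transmute(joined, .data$outcome_id, .data$exposure_category, .data$pr,
                     field = "pf_pct", computed = .data$pf_pct_computed,
                     golden = .data$pf_pct_golden, flag = .data$known_discrepancy),
    dplyr::transmute(joined, .data$outcome_id, .data$exposure_category, .data$pr,
                     field = "parp_pct", computed = .data$parp_pct_computed,
                     golden = .data$parp_pct_golden, flag = .data$known_discrepancy),
    dplyr::transmute(joined, .data$outcome_id, .data$exposure_category, .data$pr,
                     field = "preventable_dalys",
                     computed = .data$preventable_dalys_rounded,
                     golden = .data$preventable_dalys_golden,
                     flag = .data$known_discrepancy),
    dplyr::transmute(joined, .data$outcome_id, .data$exposure_category, .data$pr,
                     field = "attributable_dalys",
                     computed = .data$attributable_dalys_rounded,
                     golden = .data$attributable_dalys_golden,
                     flag = .data$known_discrepancy)
  )
  long$is_known <- mapply(
    function(field, flag) field %in% strsplit(flag, ";")[[1]],
    long$field, long$flag
  )
  mismatch <- long[long$computed != long$golden, ]
  list(
    unexplained = dplyr::select(mismatch[!mismatch$is_known, ], -"flag", -"is_known"),
    known = dplyr::select(long[long$is_known, ], -"flag", -"is_known")
  )
}

#' Plot preventable and attributable DALYs by scenario
#'
#' Stacked-style bar chart of the burden cells: per outcome, the DALYs
#' preventable with high intake (or attributable to low intake) at each
#' exposure prevalence, faceted by exposure category.
#'
#' @param object A `burden_report`.
#' @param measure `"preventable"` or `"attributable"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot burden_report
#' @export
autoplot.burden_report <- function(object, measure = c("preventable", "attributable"), ...) {
  measure <- match.arg(measure)
  col <- paste0(measure, "_dalys")
  df <- dplyr::mutate(object$burden,
                      scenario = paste0("Pr ", formatC(100 * .data$pr, format = "fg"), "%"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome_id, y = .data[[col]],
                                   fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$exposure_category), scales = "free_y") +
    ggplot2::labs(x = NULL, y = paste(measure, "DALYs (person-years)"),
                  fill = "Exposure prevalence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||%
NULL
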