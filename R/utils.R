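#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when formatting fraction and
#' burden tables for display. Base R's [round()] rounds half to even
#' (banker's rounding), which does not reproduce values such as 2.58% from
#' 0.0257879...; half-up rounding does.
#'
#' A small relative guard compensates for binary floating point: products
#' such as 0.0135 * 4275100 are exactly 57713.85 in decimal arithmetic but
#' sit a few ulps below the .5 boundary as doubles, and must still round up.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return `x` rounded half away from zero to `digits` decimals.
#' @examples
#' round_half_up(2.575, 2) # 2.58
#' round(2.575, 2)         # 2.57 under round-half-even
#' @export
round_half_up <- function(x, digits = 0) {
  z <- x * 10^digits
  sign(z) * floor(abs(z) + 0.5 + abs(z) * 1e-9) / 10^digits
}

#' Format a proportion as a percent string
#'
#' @param x Proportion in `[0, 1]`.
#' @param digits Decimal places in the percent (default 2).
#' @return Character vector like `"2.58%"`.
#' @export
format_pct <- function(x, digits = 2) {
  paste0(formatC(round_half_up(100 * x, digits), format = "f", digits = digits), "%")
}

#' Format a DALY count for human-readable tables
#'
#' One decimal place, half-up, with thousands separators (e.g. `"33,318.1"`).
#'
#' @param x Person-years.
#' @param digits Decimal places (default 1).
#' @return Character vector.
#' @export
format_daly <- function(x, digits = 1) {
  formatC(round_half_up(x, digits), format = "f", digits = digits, big.mark = ",")
}

# single abort helper so error classes are consistent across modules
db_abort <- function(msg, class) {
  rlang::abort(msg, class = c(class, "dairyburden_error"))
}

# raise a schema error for absent columns before readr's typed parse,
# so missing-column diagnostics name the column rather than warn
check_header <- function(path, required) {
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    db_abort(
      sprintf("%s is missing required column(s): %s",
              basename(path), paste(missing, collapse = ", ")),
      "dairyburden_schema_error"
    )
  }
  invisible(header)
}

stopifnot_scalar_prob <- function(x, name, open_left = TRUE, closed_right = TRUE) {
  bad <- !is.numeric(x) | is.na(x) |
    (if (open_left) x <= 0 else x < 0) |
    (if (closed_right) x > 1 else x >= 1)
  if (any(bad)) {
    db_abort(
      sprintf("`%s` must lie in %s0, 1%s; offending value(s): %s",
              name, if (open_left) "(" else "[", if (closed_right) "]" else ")",
              paste(utils::head(x[bad], 3), collapse = ", ")),
      "dairyburden_domain_error"
    )
  }
  invisible(x)
}
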