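# Calendar months are handled at "YYYY-MM" resolution everywhere; deflation
# and annual aggregation never need day-of-month.

month_regex <- "^[0-9]{4}-(0[1-9]|1[0-2])$"

is_month <- function(x) {
  !is.na(x) & grepl(month_regex, x)
}

# linear month index (12 * year + month - 1); differences give month gaps
month_index <- function(x) {
  bad <- !is_month(x)
  if (any(bad)) {
    abort(paste0("not a calendar month in 'YYYY-MM' form: ",
                 paste(unique(x[bad]), collapse = ", ")))
  }
  yr <- as.integer(substr(x, 1, 4))
  mo <- as.integer(substr(x, 6, 7))
  12L * yr + mo - 1L
}

month_from_index <- function(i) {
  sprintf("%04d-%02d", i %/% 12L, i %% 12L + 1L)
}

#' Sequence of calendar months
#'
#' @param from,to Months as `"YYYY-MM"` strings, `from <= to`.
#' @return Character vector of consecutive months, inclusive.
#' @export
#' @examples
#' month_seq("2018-11", "2019-02")
month_seq <- function(from, to) {
  a <- month_index(from)
  b <- month_index(to)
  if (a > b) abort("'from' month is after 'to' month")
  month_from_index(seq(a, b))
}

month_year <- function(x) as.integer(substr(x, 1, 4))

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves moved away from zero,
#' the convention used for all displayed percentages and unit counts (base
#' `round()` rounds halves to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5), 0)   # 1, 2, -1
#' round_half_away(c(0.125, -0.125), 2)    # 0.13, -0.13
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- rlang::`%||%`
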