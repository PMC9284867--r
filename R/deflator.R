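# Consumer-price-index deflation. Prices are adjusted to a common reference
# month by the index ratio idx[ref] / idx[month]; the series must cover every
# purchase month and the reference month, with contiguous months.

#' Read a monthly price-index series
#'
#' @param path Path to a CSV with header `month,index_value`, months in
#'   `YYYY-MM` form, strictly positive index values and no gaps.
#' @return A tibble ordered by month.
#' @export
read_price_index <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  idx <- readr::read_csv(path, col_types = readr::cols(month = "c",
                                                       index_value = "d"),
                         show_col_types = FALSE)
  if (!identical(names(idx), c("month", "index_value"))) {
    abort(paste0("malformed header in ", path,
                 " (expected month,index_value)"))
  }
  validate_price_index(idx)
}

validate_price_index <- function(idx) {
  if (any(!is_month(idx$month))) abort("index months must be 'YYYY-MM'")
  if (anyDuplicated(idx$month)) abort("duplicate months in index series")
  if (any(is.na(idx$index_value) | idx$index_value <= 0)) {
    abort("index values must be positive")
  }
  idx <- arrange(idx, month_index(.data$month))
  gaps <- diff(month_index(idx$month))
  if (any(gaps != 1L)) abort("index series has gaps between months")
  idx
}

#' Expand annual index factors to a monthly series
#'
#' When only annual index values are available, expands them to a step-wise
#' monthly series in which the value is constant within each calendar year.
#'
#' @param annual A data frame with columns `year` and `index_value`
#'   (consecutive years, positive values).
#' @return A monthly index tibble as returned by [read_price_index()].
#' @export
#' @examples
#' expand_annual_index(data.frame(year = 2018:2019, index_value = c(100, 104)))
expand_annual_index <- function(annual) {
  stopifnot(all(c("year", "index_value") %in% names(annual)))
  annual <- annual[order(annual$year), ]
  if (any(diff(annual$year) != 1L)) abort("annual index years must be consecutive")
  validate_price_index(tibble(
    month = sprintf("%04d-%02d", rep(annual$year, each = 12L), 1:12),
    index_value = rep(annual$index_value, each = 12L)
  ))
}

index_lookup <- function(months, idx, what = "month") {
  pos <- match(months, idx$month)
  if (anyNA(pos)) {
    missing <- unique(months[is.na(pos)])
    abort(paste0("price index does not cover ", what, " ",
                 paste(missing, collapse = ", ")))
  }
  idx$index_value[pos]
}

#' Deflate a nominal price to a reference month
#'
#' Returns `nominal * idx[ref] / idx[month]`. Adjusting a price already in the
#' reference month is the identity, and adjusting to `ref1` and then on to
#' `ref2` equals adjusting directly to `ref2`.
#'
#' @param nominal Nominal price(s), positive.
#' @param month Month(s) of the nominal price, `"YYYY-MM"` (recycled against
#'   `nominal`).
#' @param ref Reference month.
#' @param index Monthly index tibble covering `month` and `ref`.
#' @return Adjusted price(s) in reference-month currency.
#' @export
#' @examples
#' idx <- data.frame(month = month_seq("2019-01", "2019-07"),
#'                   index_value = c(100, 101, 102, 103, 104, 105, 110))
#' adjust_price(100, "2019-01", "2019-07", idx)  # 110
adjust_price <- function(nominal, month, ref, index) {
  nominal * index_lookup(ref, index, "reference month") /
    index_lookup(month, index)
}

#' Deflate the unit prices of a purchase ledger
#'
#' Applies [adjust_price()] to every record. Quantities are untouched; the
#' nominal price is preserved in `nominal_unit_price`.
#'
#' @param records Purchase-record tibble.
#' @param index Monthly index tibble covering all purchase months and `ref`.
#' @param ref Reference month, `"YYYY-MM"`.
#' @return `records` with `unit_price` in reference-month currency and an
#'   additional `nominal_unit_price` column.
#' @export
adjust_records <- function(records, index, ref) {
  nominal <- if ("nominal_unit_price" %in% names(records)) {
    abort("records appear to be deflated already (nominal_unit_price present)")
  } else {
    records$unit_price
  }
  records$nominal_unit_price <- nominal
  records$unit_price <- adjust_price(nominal, records$purchase_date, ref, index)
  records
}
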