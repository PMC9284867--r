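# Milligram standardisation and per-stratum aggregation. A stratum is a
# medicine x category cell, optionally split by calendar year; its weighted
# average price per mg (WAP/mg) is total expenditure over total mg.

#' Standardise purchase volume to milligrams
#'
#' Several injectable antineoplastics have no defined daily dose, so volumes
#' are compared in mg of active ingredient: `quantity_units * strength_mg`.
#' Adds `volume_mg` (and `strength_mg`) columns.
#'
#' @param records Purchase-record tibble.
#' @param master Medicine master tibble (see [read_medicine_master()]).
#' @return `records` with `strength_mg` and `volume_mg` columns.
#' @export
#' @examples
#' rec <- tibble::tibble(medicine_code = "x", quantity_units = 10L)
#' mst <- tibble::tibble(medicine_code = "x", strength_mg = 20)
#' add_volume_mg(rec, mst)$volume_mg  # 200
add_volume_mg <- function(records, master) {
  unknown <- setdiff(unique(records$medicine_code), master$medicine_code)
  if (length(unknown)) {
    abort(paste0("medicine codes missing from master: ",
                 paste(unknown, collapse = ", ")))
  }
  records %>%
    left_join(select(master, "medicine_code", "strength_mg"),
              by = "medicine_code") %>%
    mutate(volume_mg = .data$quantity_units * .data$strength_mg)
}

#' Aggregate a ledger into WAP/mg strata
#'
#' Sums milligram volume and (deflated) expenditure over the records of each
#' stratum and derives the weighted average price per mg,
#' `wap_per_mg = expenditure / volume_mg`. Empty strata are omitted.
#'
#' @param records Deflated purchase-record tibble (see [adjust_records()]).
#' @param master Medicine master tibble.
#' @param by Grouping columns, a subset of
#'   `c("medicine_code", "year", "category")`. Defaults to the full
#'   medicine x year x category split used by the avoidable-expenditure
#'   analysis; drop `"year"` for whole-window tables.
#' @return A tibble with the grouping columns plus `volume_mg`, `expenditure`
#'   and `wap_per_mg`, sorted by the grouping columns (categories in the fixed
#'   ME, MH, MD, OI order).
#' @export
aggregate_strata <- function(records, master,
                             by = c("medicine_code", "year", "category")) {
  allowed <- c("medicine_code", "year", "category")
  if (!length(by) || !all(by %in% allowed)) {
    abort("by must be a non-empty subset of medicine_code, year, category")
  }
  dat <- add_volume_mg(records, master)
  if ("year" %in% by) dat$year <- month_year(dat$purchase_date)
  out <- dat %>%
    group_by(across(all_of(by))) %>%
    summarise(volume_mg = sum(.data$volume_mg),
              expenditure = sum(.data$quantity_units * .data$unit_price),
              .groups = "drop") %>%
    mutate(wap_per_mg = .data$expenditure / .data$volume_mg)
  if ("category" %in% by) {
    out$category <- factor(out$category, levels = category_levels())
  }
  out <- arrange(out, across(all_of(by)))
  if ("category" %in% by) out$category <- as.character(out$category)
  out
}

#' Percentage shares of a margin
#'
#' Computes each stratum's percentage of a margin total for the chosen
#' measure. Shares are computed on full-precision aggregates and rounded
#' half-away-from-zero to two decimals only at the end, so shares across a
#' complete margin sum to 100 up to rounding slack.
#'
#' @param aggregates A stratum tibble from [aggregate_strata()] (any level).
#' @param margin `"grand_total"` (share of the overall total),
#'   `"by_medicine"` (within each medicine) or `"by_category"` (within each
#'   category).
#' @param measure `"expenditure"` or `"volume_mg"`.
#' @return `aggregates` with a `share` column (percent, 2 decimals).
#' @export
share <- function(aggregates,
                  margin = c("grand_total", "by_medicine", "by_category"),
                  measure = c("expenditure", "volume_mg")) {
  margin <- match.arg(margin)
  measure <- match.arg(measure)
  if (!measure %in% names(aggregates)) {
    abort(paste0("aggregates lack a '", measure, "' column"))
  }
  key <- switch(margin,
                grand_total = character(0),
                by_medicine = "medicine_code",
                by_category = "category")
  if (length(key) && !all(key %in% names(aggregates))) {
    abort(paste0("margin '", margin, "' needs column(s): ",
                 paste(key, collapse = ", ")))
  }
  aggregates %>%
    group_by(across(all_of(key))) %>%
    mutate(share = round_half_away(
      100 * .data[[measure]] / sum(.data[[measure]]), 2)) %>%
    ungroup()
}
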