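# Lowest-price counterfactual. For each medicine and year the benchmark is
# the lowest WAP/mg among purchasing categories; buying the same mg volume at
# that price defines the counterfactual spend, and the excess of actual over
# counterfactual spend is the avoidable expenditure. Dividing it by the
# benchmark WAP/mg gives the additional mg (and, via the strength, dispensing
# units) that the same budget could have bought.

#' Benchmark (lowest) WAP/mg per medicine and year
#'
#' Among the categories with positive volume in a given medicine x year cell,
#' finds the minimum `wap_per_mg` and the category paying it. Exact ties are
#' broken deterministically by the fixed category order ME, MH, MD, OI, with a
#' warning.
#'
#' @param aggregates Medicine x year x category strata from
#'   [aggregate_strata()].
#' @return A tibble with `medicine_code`, `year`, `benchmark_wap`,
#'   `benchmark_category`.
#' @export
benchmark_wap <- function(aggregates) {
  need <- c("medicine_code", "year", "category", "volume_mg", "wap_per_mg")
  if (!all(need %in% names(aggregates))) {
    abort("aggregates must be at the medicine x year x category level")
  }
  pos <- filter(aggregates, .data$volume_mg > 0)
  pos$category <- factor(pos$category, levels = category_levels())
  ties <- pos %>%
    group_by(.data$medicine_code, .data$year) %>%
    summarise(n_min = sum(.data$wap_per_mg == min(.data$wap_per_mg)),
              .groups = "drop")
  if (any(ties$n_min > 1)) {
    tied <- ties[ties$n_min > 1, ]
    warn(paste0("benchmark WAP/mg tie broken by category order for: ",
                paste(sprintf("%s/%d", tied$medicine_code, tied$year),
                      collapse = ", ")))
  }
  pos %>%
    group_by(.data$medicine_code, .data$year) %>%
    arrange(.data$category, .by_group = TRUE) %>%
    slice_min(.data$wap_per_mg, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    mutate(benchmark_category = as.character(.data$category)) %>%
    select("medicine_code", "year", benchmark_wap = "wap_per_mg",
           "benchmark_category")
}

#' Additional quantity purchasable at the benchmark price
#'
#' Converts an avoidable-expenditure amount into the extra quantity the same
#' money would have bought at the benchmark WAP/mg:
#' `additional_mg = avoidable / benchmark_wap`, and
#' `additional_units = round(additional_mg / strength_mg)` with halves away
#' from zero.
#'
#' @param avoidable Avoidable expenditure (vectorised; `NA` passes through).
#' @param benchmark_wap Benchmark WAP/mg.
#' @param strength_mg mg of active ingredient per dispensing unit.
#' @return A tibble with `additional_mg` and `additional_units`.
#' @export
#' @examples
#' additional_quantity(50, 1, 10)  # 50 mg, 5 units
additional_quantity <- function(avoidable, benchmark_wap, strength_mg) {
  mg <- avoidable / benchmark_wap
  tibble(additional_mg = mg,
         additional_units = as.integer(round_half_away(mg / strength_mg)))
}

#' Avoidable expenditure per stratum
#'
#' Joins each medicine x year x category stratum to its within-year benchmark
#' and computes the counterfactual spend at the benchmark price,
#' `counterfactual = expenditure * benchmark_wap / actual_wap`
#' (equivalently `volume_mg * benchmark_wap`), the avoidable expenditure
#' `actual - counterfactual`, and the additional purchasable quantity. The
#' benchmark category's own cell is `NA` by convention (its avoidable
#' expenditure is nil).
#'
#' @param aggregates Medicine x year x category strata from
#'   [aggregate_strata()].
#' @param master Medicine master tibble (for strengths).
#' @return A tibble with one row per stratum: `medicine_code`, `year`,
#'   `category`, `actual_expenditure`, `actual_wap`, `benchmark_wap`,
#'   `benchmark_category`, `counterfactual_expenditure`,
#'   `avoidable_expenditure`, `additional_mg`, `additional_units`.
#' @export
avoidable_expenditure <- function(aggregates, master) {
  bench <- benchmark_wap(aggregates)
  out <- aggregates %>%
    filter(.data$volume_mg > 0) %>%
    inner_join(bench, by = c("medicine_code", "year")) %>%
    left_join(select(master, "medicine_code", "strength_mg"),
              by = "medicine_code") %>%
    mutate(
      counterfactual_expenditure =
        .data$expenditure * .data$benchmark_wap / .data$wap_per_mg,
      avoidable_expenditure =
        ifelse(.data$category == .data$benchmark_category, NA_real_,
               .data$expenditure - .data$counterfactual_expenditure)
    )
  qty <- additional_quantity(out$avoidable_expenditure, out$benchmark_wap,
                             out$strength_mg)
  out %>%
    mutate(additional_mg = qty$additional_mg,
           additional_units = qty$additional_units) %>%
    select("medicine_code", "year", "category",
           actual_expenditure = "expenditure", actual_wap = "wap_per_mg",
           "benchmark_wap", "benchmark_category",
           "counterfactual_expenditure", "avoidable_expenditure",
           "additional_mg", "additional_units")
}

#' Additional units as a share of total purchased units
#'
#' Expresses the additional purchasable units of each medicine as a percentage
#' of the total units actually purchased over the window (total mg divided by
#' the strength), rounded to two decimals.
#'
#' @param avoidable Avoidable-expenditure tibble from
#'   [avoidable_expenditure()] (or any tibble with `medicine_code` and
#'   `additional_units`).
#' @param volume_totals Tibble with `medicine_code` and total `volume_mg` over
#'   the window (e.g. [aggregate_strata()] with `by = "medicine_code"`).
#' @param master Medicine master tibble.
#' @return A tibble with `medicine_code`, `additional_units`,
#'   `purchased_units` and `additional_share` (percent).
#' @export
additional_share <- function(avoidable, volume_totals, master) {
  avoidable %>%
    group_by(.data$medicine_code) %>%
    summarise(additional_units = sum(.data$additional_units, na.rm = TRUE),
              .groups = "drop") %>%
    inner_join(select(volume_totals, "medicine_code", "volume_mg"),
               by = "medicine_code") %>%
    inner_join(select(master, "medicine_code", "strength_mg"),
               by = "medicine_code") %>%
    mutate(purchased_units = .data$volume_mg / .data$strength_mg,
           additional_share = round_half_away(
             100 * .data$additional_units / .data$purchased_units, 2)) %>%
    select("medicine_code", "additional_units", "purchased_units",
           "additional_share")
}
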