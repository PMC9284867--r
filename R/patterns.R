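# Volume-price pattern classification. The qualitative dichotomy between a
# "market" trajectory (annual volume and WAP/mg inversely related) and an
# "inelastic" one (no systematic relation) is made operational with a rank
# correlation over the annual series and two configurable thresholds.

pattern_labels <- c("market", "inelastic", "indeterminate",
                    "insufficient_data")

# Spearman rho robust to ties; both-axis zero variance convention: a series
# with no rank variation in either variable carries no ordering information
# and is assigned rho = 0 (literal price constancy is the paradigm of
# inelasticity).
rank_rho <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(0)
  cor(rx, ry, method = "pearson")
}

#' Classify volume-price trajectories
#'
#' For each medicine x category pair, computes the rank correlation `rho`
#' between annual milligram volume and annual WAP/mg over the years with
#' positive volume, and labels the trajectory:
#'
#' * `market` when `rho <= pattern_market_threshold` (default -0.5): volume
#'   and price are inversely related, the expected competitive pattern;
#' * `inelastic` when `|rho| < pattern_inelastic_threshold` (default 0.3):
#'   volume does not appear to influence price;
#' * `indeterminate` otherwise;
#' * `insufficient_data` when fewer than `pattern_min_years` usable years
#'   (default 4) are available (`rho` is still reported when computable).
#'
#' The label is invariant to positive rescaling of either axis and to the
#' order of years (the correlation pairs values, not time order). A price
#' series with zero variance is assigned `rho = 0`.
#'
#' @param aggregates Medicine x year x category strata from
#'   [aggregate_strata()].
#' @param config A [study_config()] supplying the thresholds.
#' @return A tibble with `medicine_code`, `category`, `rho`, `n_years`,
#'   `label`, of class `"pattern_classification"`.
#' @export
classify_patterns <- function(aggregates, config = study_config()) {
  need <- c("medicine_code", "year", "category", "volume_mg", "wap_per_mg")
  if (!all(need %in% names(aggregates))) {
    abort("aggregates must be at the medicine x year x category level")
  }
  if (anyDuplicated(aggregates[c("medicine_code", "category", "year")])) {
    abort("years must be distinct within each medicine x category series")
  }
  out <- aggregates %>%
    filter(.data$volume_mg > 0) %>%
    group_by(.data$medicine_code, .data$category) %>%
    summarise(
      rho = if (n() >= 2) rank_rho(.data$volume_mg, .data$wap_per_mg)
            else NA_real_,
      n_years = n(),
      .groups = "drop") %>%
    mutate(label = dplyr::case_when(
      .data$n_years < config$pattern_min_years ~ "insufficient_data",
      .data$rho <= config$pattern_market_threshold ~ "market",
      abs(.data$rho) < config$pattern_inelastic_threshold ~ "inelastic",
      TRUE ~ "indeterminate"))
  class(out) <- c("pattern_classification", class(out))
  out
}
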