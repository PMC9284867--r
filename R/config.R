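#' Study configuration
#'
#' Bundles the settings that define an analysis run: the study window, the
#' inclusion rule for medicines, the deflation reference month and the
#' thresholds used by the volume-price pattern classifier.
#'
#' The default inclusion rule keeps a medicine only if the Ministry of Health
#' bought it in at least `min_years_purchased` distinct calendar years of the
#' window. The driving category is configurable so that synthetic studies can
#' vary it.
#'
#' @param window_start,window_end First and last calendar month of the study
#'   window, `"YYYY-MM"`. Defaults cover January 2013 to December 2019.
#' @param min_years_purchased Minimum number of distinct calendar years with at
#'   least one qualifying purchase for a medicine to be included (default 5).
#' @param inclusion_category Purchaser category whose purchases drive the
#'   inclusion rule; one of `"ME"`, `"MH"`, `"MD"`, `"OI"` (default `"MH"`).
#' @param reference_month Month all prices are deflated to (default
#'   `"2019-07"`).
#' @param pattern_market_threshold Rank-correlation value at or below which a
#'   volume-price trajectory is labelled `market` (default -0.5).
#' @param pattern_inelastic_threshold Absolute rank-correlation value below
#'   which a trajectory is labelled `inelastic` (default 0.3).
#' @param pattern_min_years Minimum number of usable years for a trajectory to
#'   be classified at all (default 4).
#'
#' @return A list of class `"study_config"`.
#' @export
#' @examples
#' cfg <- study_config()
#' cfg$reference_month
study_config <- function(window_start = "2013-01",
                         window_end = "2019-12",
                         min_years_purchased = 5L,
                         inclusion_category = "MH",
                         reference_month = "2019-07",
                         pattern_market_threshold = -0.5,
                         pattern_inelastic_threshold = 0.3,
                         pattern_min_years = 4L) {
  if (!is_month(window_start) || !is_month(window_end)) {
    abort("window_start and window_end must be 'YYYY-MM' months")
  }
  if (month_index(window_start) >= month_index(window_end)) {
    abort("window_start must be before window_end")
  }
  if (!is_month(reference_month)) {
    abort("reference_month must be a 'YYYY-MM' month")
  }
  if (!inclusion_category %in% category_levels()) {
    abort(paste0("inclusion_category must be one of: ",
                 paste(category_levels(), collapse = ", ")))
  }
  n_years <- month_year(window_end) - month_year(window_start) + 1L
  min_years_purchased <- as.integer(min_years_purchased)
  if (is.na(min_years_purchased) ||
      min_years_purchased < 1L || min_years_purchased > n_years) {
    abort(sprintf("min_years_purchased must be between 1 and %d", n_years))
  }
  if (!is.numeric(pattern_market_threshold) ||
      !is.numeric(pattern_inelastic_threshold) ||
      pattern_inelastic_threshold < 0) {
    abort("pattern thresholds must be numeric (inelastic threshold >= 0)")
  }
  structure(
    list(window_start = window_start,
         window_end = window_end,
         min_years_purchased = min_years_purchased,
         inclusion_category = inclusion_category,
         reference_month = reference_month,
         pattern_market_threshold = pattern_market_threshold,
         pattern_inelastic_threshold = pattern_inelastic_threshold,
         pattern_min_years = as.integer(pattern_min_years)),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration\n")
  cat("  window:           ", x$window_start, "to", x$window_end, "\n")
  cat("  inclusion rule:   >=", x$min_years_purchased,
      "of", month_year(x$window_end) - month_year(x$window_start) + 1L,
      "years, category", x$inclusion_category, "\n")
  cat("  reference month:  ", x$reference_month, "\n")
  cat("  pattern labels:    market <=", x$pattern_market_threshold,
      "; inelastic |rho| <", x$pattern_inelastic_threshold,
      "; min years", x$pattern_min_years, "\n")
  invisible(x)
}

#' Read a study configuration from a YAML file
#'
#' Flat keys matching the arguments of [study_config()]; missing keys fall
#' back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `"study_config"` object.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("read_study_config() needs the 'yaml' package")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    warn(paste0("ignoring unknown config keys: ", paste(extra, collapse = ", ")))
  }
  do.call(study_config, vals[intersect(names(vals), known)])
}
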