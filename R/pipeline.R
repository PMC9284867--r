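# End-to-end orchestration: ingest -> window filter -> eligibility filter ->
# medicine selection -> deflation -> aggregation -> shares -> avoidable
# expenditure -> pattern classification, with a run manifest auditing the
# filter cascade.

#' Run the full procurement price analysis
#'
#' Executes every pipeline stage on a purchase ledger and returns a
#' `"procurement_run"` object holding the whole-window volume and spending
#' tables (with within-medicine percentage shares), the per-year avoidable
#' expenditure table, the volume-price pattern classification, the annual
#' strata behind them, and a manifest of record counts before and after each
#' filter. Inputs may be file paths (validated CSVs) or tibbles already in
#' the documented schemas.
#'
#' @param purchases Ledger CSV path or purchase-record tibble.
#' @param index Price-index CSV path or tibble (`month,index_value`).
#' @param master Medicine master CSV path or tibble.
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, the output tables and a
#'   `manifest.json` are written there via [write_run_outputs()].
#' @param skip_invalid Passed to [read_purchases()].
#' @return A list of class `"procurement_run"` with elements `config`,
#'   `manifest`, `medicines`, `volume` (medicine x category mg with shares),
#'   `spending` (medicine x category expenditure with shares), `avoidable`,
#'   `additional` (per-medicine additional-unit shares), `patterns`,
#'   `annual` (medicine x year x category strata).
#' @export
run_procurement_analysis <- function(purchases, index, master,
                                     config = study_config(),
                                     out_dir = NULL, skip_invalid = FALSE) {
  stopifnot(inherits(config, "study_config"))
  digests <- character(0)
  if (is.character(master)) {
    digests["master"] <- unname(tools::md5sum(master))
    master <- read_medicine_master(master)
  }
  if (is.character(purchases)) {
    digests["purchases"] <- unname(tools::md5sum(purchases))
    purchases <- read_purchases(purchases, master, skip_invalid = skip_invalid)
  }
  if (is.character(index)) {
    digests["index"] <- unname(tools::md5sum(index))
    index <- read_price_index(index)
  } else {
    index <- validate_price_index(index)
  }

  n_read <- nrow(purchases)
  idx <- month_index(purchases$purchase_date)
  in_window <- purchases[idx >= month_index(config$window_start) &
                           idx <= month_index(config$window_end), ]
  eligible <- filter_eligible(in_window)
  codes <- select_medicines(eligible, config)
  selected <- filter(eligible, .data$medicine_code %in% codes)

  deflated <- adjust_records(selected, index, config$reference_month)
  annual <- aggregate_strata(deflated, master)
  whole <- aggregate_strata(deflated, master, by = c("medicine_code",
                                                     "category"))
  volume <- share(whole, margin = "by_medicine", measure = "volume_mg")
  spending <- share(whole, margin = "by_medicine", measure = "expenditure")
  avoidable <- avoidable_expenditure(annual, master)
  med_totals <- aggregate_strata(deflated, master, by = "medicine_code")
  additional <- additional_share(avoidable, med_totals, master)
  patterns <- classify_patterns(annual, config)

  manifest <- list(
    config = unclass(config),
    input_digests = as.list(digests),
    counts = list(records_read = n_read,
                  records_in_window = nrow(in_window),
                  records_eligible = nrow(eligible),
                  medicines_selected = length(codes),
                  records_analysed = nrow(selected)),
    reference_month = config$reference_month)

  run <- structure(
    list(config = config, manifest = manifest, medicines = codes,
         volume = volume, spending = spending, avoidable = avoidable,
         additional = additional, patterns = patterns, annual = annual),
    class = "procurement_run")
  if (!is.null(out_dir)) {
    run$manifest$outputs <- write_run_outputs(run, out_dir)
  }
  run
}

#' Write the output tables of a run
#'
#' Emits `table1_volume.csv` and `table2_spending.csv` (medicine x category
#' amounts and within-medicine percentage shares), `table3_avoidable.csv`
#' (long layout, `NA` literal for the benchmark category's own cells),
#' `patterns.csv`, `annual_series.csv` (the per-year strata, for external
#' plotting) and `manifest.json`. Plain decimals, no locale formatting, so
#' repeated runs on the same inputs are byte-identical.
#'
#' @param run A `"procurement_run"`.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_run_outputs <- function(run, out_dir) {
  stopifnot(inherits(run, "procurement_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(table1 = "table1_volume.csv", table2 = "table2_spending.csv",
             table3 = "table3_avoidable.csv", patterns = "patterns.csv",
             annual = "annual_series.csv", manifest = "manifest.json")
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)
  readr::write_csv(run$volume, paths["table1"])
  readr::write_csv(run$spending, paths["table2"])
  table3 <- run$avoidable %>%
    mutate(avoidable_expenditure =
             round_half_away(.data$avoidable_expenditure)) %>%
    select("medicine_code", "year", "category", "avoidable_expenditure",
           "additional_units", "benchmark_category")
  readr::write_csv(table3, paths["table3"], na = "NA")
  readr::write_csv(run$patterns, paths["patterns"])
  readr::write_csv(run$annual, paths["annual"])
  manifest <- run$manifest
  manifest$outputs <- as.list(setNames(as.character(paths), names(paths)))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

#' @export
print.procurement_run <- function(x, ...) {
  cts <- x$manifest$counts
  cat("Procurement price analysis run\n")
  cat(sprintf("  window %s..%s, prices at %s\n", x$config$window_start,
              x$config$window_end, x$config$reference_month))
  cat(sprintf("  records: %d read, %d in window, %d eligible, %d analysed\n",
              cts$records_read, cts$records_in_window, cts$records_eligible,
              cts$records_analysed))
  cat(sprintf("  medicines selected: %d (%s)\n", length(x$medicines),
              paste(x$medicines, collapse = ", ")))
  cat(sprintf("  total spending: %.2f | total avoidable: %.2f\n",
              sum(x$spending$expenditure),
              sum(x$avoidable$avoidable_expenditure, na.rm = TRUE)))
  invisible(x)
}

#' Tidy a procurement run
#'
#' Returns the per medicine x year x category avoidable-expenditure table,
#' the run's central result, as a tibble.
#'
#' @param x A `"procurement_run"`.
#' @param ... Unused.
#' @return A tibble (see [avoidable_expenditure()]).
#' @export
tidy.procurement_run <- function(x, ...) {
  as_tibble(x$avoidable)
}

#' Glance at a procurement run
#'
#' @param x A `"procurement_run"`.
#' @param ... Unused.
#' @return A one-row tibble with record counts, the number of selected
#'   medicines, total (deflated) expenditure, total avoidable expenditure,
#'   total additional purchasable units and the reference month.
#' @export
glance.procurement_run <- function(x, ...) {
  tibble(
    n_records = x$manifest$counts$records_read,
    n_eligible = x$manifest$counts$records_eligible,
    n_analysed = x$manifest$counts$records_analysed,
    n_medicines = length(x$medicines),
    total_expenditure = sum(x$spending$expenditure),
    total_avoidable = sum(x$avoidable$avoidable_expenditure, na.rm = TRUE),
    total_additional_units = sum(x$avoidable$additional_units, na.rm = TRUE),
    reference_month = x$config$reference_month)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
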