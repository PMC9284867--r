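# Purchase-ledger ingestion: strict CSV schemas, row-level validation and the
# two inclusion rules (active/competitive records; medicines bought by the
# inclusion category in >= k distinct years).

purchases_header <- c("medicine_code", "purchase_date", "category",
                      "entity_id", "quantity_units", "unit_price",
                      "procurement_type", "status")
master_header <- c("medicine_code", "name", "strength_mg", "dosage_form")

dosage_forms <- c("tablet", "capsule", "ampoule")
procurement_types <- c("competitive", "waiver", "not_required")
statuses <- c("active", "inactive")

read_csv_strict <- function(path, header, col_types) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  got <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               show_col_types = FALSE))
  if (!identical(got, header)) {
    abort(paste0("malformed header in ", path, "\n  expected: ",
                 paste(header, collapse = ","), "\n  found:    ",
                 paste(got, collapse = ",")))
  }
  readr::read_csv(path, col_types = col_types, show_col_types = FALSE)
}

#' Read a medicine master list
#'
#' The master list maps each medicine code to its name, strength of active
#' ingredient per dispensing unit (mg) and dosage form. Codes must be unique;
#' medicines sold as several forms of equal strength are pooled under one code.
#'
#' @param path Path to a CSV with header
#'   `medicine_code,name,strength_mg,dosage_form`.
#' @return A tibble with one row per medicine code.
#' @export
read_medicine_master <- function(path) {
  master <- read_csv_strict(path, master_header,
                            readr::cols(medicine_code = "c", name = "c",
                                        strength_mg = "d", dosage_form = "c"))
  if (anyDuplicated(master$medicine_code)) {
    abort("duplicate medicine_code in master list")
  }
  if (any(is.na(master$strength_mg) | master$strength_mg <= 0)) {
    abort("strength_mg must be positive for every medicine")
  }
  bad <- setdiff(unique(master$dosage_form), dosage_forms)
  if (length(bad)) {
    abort(paste0("unknown dosage_form: ", paste(bad, collapse = ", ")))
  }
  master
}

validate_purchases <- function(records, master) {
  problems <- list(
    tibble(row = which(!records$medicine_code %in% master$medicine_code),
           problem = "unknown medicine_code"),
    tibble(row = which(!is_month(records$purchase_date)),
           problem = "unparseable purchase_date (expected YYYY-MM)"),
    tibble(row = which(!records$category %in% category_levels()),
           problem = "unknown category token"),
    tibble(row = which(is.na(records$quantity_units) |
                         records$quantity_units < 1),
           problem = "quantity_units must be a positive integer"),
    tibble(row = which(is.na(records$unit_price) | records$unit_price <= 0),
           problem = "unit_price must be positive"),
    tibble(row = which(!records$procurement_type %in% procurement_types),
           problem = "unknown procurement_type"),
    tibble(row = which(!records$status %in% statuses),
           problem = "unknown status")
  )
  bind_rows(problems) %>% arrange(.data$row)
}

#' Read and validate a purchase ledger
#'
#' One row per procurement event. Every row is checked against the medicine
#' master list and the field invariants (known code, parseable `YYYY-MM` date,
#' positive quantity and price, known category/procurement/status tokens).
#' Invalid rows abort the read with row-level diagnostics unless
#' `skip_invalid = TRUE`, in which case they are dropped with a warning and
#' returned in the `"rejections"` attribute.
#'
#' @param path Path to a CSV with header
#'   `medicine_code,purchase_date,category,entity_id,quantity_units,unit_price,procurement_type,status`.
#' @param master Medicine master tibble from [read_medicine_master()].
#' @param skip_invalid Drop invalid rows instead of failing (default `FALSE`).
#' @return A tibble of purchase records in file order. When rows were skipped,
#'   the attribute `"rejections"` holds a tibble of row numbers and reasons.
#' @export
read_purchases <- function(path, master, skip_invalid = FALSE) {
  records <- read_csv_strict(
    path, purchases_header,
    readr::cols(medicine_code = "c", purchase_date = "c", category = "c",
                entity_id = "c", quantity_units = "i", unit_price = "d",
                procurement_type = "c", status = "c"))
  bad <- validate_purchases(records, master)
  if (nrow(bad) > 0) {
    msg <- paste0(nrow(bad), " invalid row(s) in ", path, ":\n",
                  paste(sprintf("  row %d: %s",
                                head(bad$row, 10), head(bad$problem, 10)),
                        collapse = "\n"),
                  if (nrow(bad) > 10) "\n  ..." else "")
    if (!skip_invalid) abort(msg)
    warn(paste0("dropping ", length(unique(bad$row)), " invalid row(s) of ",
                nrow(records)))
    records <- records[-unique(bad$row), , drop = FALSE]
    attr(records, "rejections") <- bad
  }
  records
}

#' Write a purchase ledger
#'
#' Inverse of [read_purchases()]: writes the documented CSV schema so that a
#' read-write-read round trip is the identity on all fields.
#'
#' @param records Purchase-record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_purchases <- function(records, path) {
  readr::write_csv(records[, purchases_header], path)
  invisible(path)
}

#' Keep only active, competitively procured purchases
#'
#' Quality is vetted during competitive bidding, so the analysis considers
#' only records with `status = "active"` and
#' `procurement_type = "competitive"`. Relative order is preserved and the
#' operation is idempotent.
#'
#' @param records Purchase-record tibble.
#' @return The eligible subset of `records`.
#' @export
filter_eligible <- function(records) {
  filter(records,
         .data$status == "active",
         .data$procurement_type == "competitive")
}

#' Select medicines by the k-of-N-years inclusion rule
#'
#' A medicine is selected when the inclusion category (by default the Ministry
#' of Health) purchased it in at least `min_years_purchased` distinct calendar
#' years of the study window. The rule counts years with at least one
#' qualifying purchase, not purchase events, so it is monotone in k.
#'
#' @param records Eligibility-filtered purchase records (see
#'   [filter_eligible()]).
#' @param config A [study_config()].
#' @return Sorted character vector of selected medicine codes.
#' @export
select_medicines <- function(records, config) {
  lo <- month_index(config$window_start)
  hi <- month_index(config$window_end)
  idx <- month_index(records$purchase_date)
  qualifying <- records[records$category == config$inclusion_category &
                          idx >= lo & idx <= hi, ]
  years <- qualifying %>%
    distinct(.data$medicine_code, year = month_year(.data$purchase_date)) %>%
    count(.data$medicine_code, name = "n_years")
  sort(years$medicine_code[years$n_years >= config$min_years_purchased])
}
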