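# Seeded generator of procurement-registry-style ledgers with known ground
# truth. Prices follow strength x base price/mg x category multiplier x
# geometric monthly inflation x multiplicative log-normal noise (mean 1);
# annual volumes are spread uniformly over the months of the year with the
# remainder assigned to the earliest months, so a fixed seed yields a
# byte-identical ledger. Because the generated index series follows the same
# geometric drift, deflation to the reference month removes it exactly and
# every downstream quantity has a closed form.

default_sim_medicines <- function() {
  tibble(
    medicine_code = c("syn_tamoxifen_20", "syn_trastuzumab_440",
                      "syn_paclitaxel_6", "syn_anastrozole_1",
                      "syn_letrozole_2.5", "syn_exemestane_25"),
    name = c("Tamoxifen (synthetic)", "Trastuzumab (synthetic)",
             "Paclitaxel (synthetic)", "Anastrozole (synthetic)",
             "Letrozole (synthetic)", "Exemestane (synthetic)"),
    strength_mg = c(20, 440, 6, 1, 2.5, 25),
    dosage_form = c("tablet", "ampoule", "ampoule", "tablet", "tablet",
                    "capsule"),
    base_price_per_mg = c(0.05, 25, 0.45, 1.2, 3, 0.7),
    annual_units = c(60000, 600, 12000, 40000, 8000, 5000),
    # number of window years with inclusion-category purchases (NA = all):
    # two medicines deliberately fail the default 5-of-7 inclusion rule
    inclusion_years = c(NA, NA, NA, NA, 4L, 3L)
  )
}

default_annual_volumes <- function(medicines, window_start, window_end) {
  years <- seq(month_year(window_start), month_year(window_end))
  weights <- c(ME = 0.45, MH = 0.30, MD = 0.08, OI = 0.17)
  grid <- tidyr::expand_grid(medicine_code = medicines$medicine_code,
                             category = category_levels(),
                             year = years)
  grid %>%
    left_join(select(medicines, "medicine_code", "annual_units",
                     "inclusion_years"),
              by = "medicine_code") %>%
    mutate(units = round(.data$annual_units * weights[.data$category] *
                           1.02^(.data$year - years[1])),
           units = ifelse(.data$category == "MH" &
                            !is.na(.data$inclusion_years) &
                            .data$year > years[1] + .data$inclusion_years - 1L,
                          0L, .data$units),
           units = as.integer(.data$units)) %>%
    select("medicine_code", "category", "year", "units")
}

#' Configuration for the synthetic ledger generator
#'
#' The defaults emulate the study conditions the package is designed around:
#' a seven-year window (2013-2019), four purchaser categories with the
#' Ministry of Education dominating volumes, category price multipliers with
#' the Ministry of Health as the cheapest buyer (multiplier 1) and the
#' Ministry of Defense the dearest, mild monthly inflation, 10% price noise
#' and a 15% contamination share of inactive or non-competitive rows. Two of
#' the six default medicines fail the 5-of-7-years inclusion rule on purpose.
#'
#' @param seed Integer seed fixing the entire ledger.
#' @param window_start,window_end Study window months, `"YYYY-MM"`.
#' @param reference_month Deflation reference month used for the closed-form
#'   truth.
#' @param medicines Tibble with `medicine_code`, `name`, `strength_mg`,
#'   `dosage_form` and `base_price_per_mg` (per-mg price of the cheapest
#'   category before inflation).
#' @param category_multipliers Named multipliers `lambda_c >= 1`, one per
#'   category, minimum exactly 1; the price a category pays is the base price
#'   scaled by its multiplier.
#' @param annual_volume_units Tibble `medicine_code, category, year, units`
#'   of annual purchase volumes in dispensing units; defaults to a volume
#'   plan derived from `medicines`.
#' @param rows_per_month Number of purchase rows each medicine x category x
#'   month cell is split into (default 1); raise it to emulate many procuring
#'   entities buying in the same month, e.g. for noise-averaging studies.
#' @param monthly_inflation Geometric monthly price drift (default 0.005,
#'   about 6.2%/year).
#' @param price_noise_cv Coefficient of variation of the multiplicative
#'   log-normal price noise (default 0.1; 0 gives exact closed-form prices).
#' @param contamination_fraction Share of the final ledger made of inactive
#'   or non-competitive rows that [filter_eligible()] must remove
#'   (default 0.15).
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 20130101,
                              window_start = "2013-01",
                              window_end = "2019-12",
                              reference_month = "2019-07",
                              medicines = default_sim_medicines(),
                              category_multipliers =
                                c(ME = 1.1, MH = 1, MD = 1.5, OI = 1.25),
                              annual_volume_units = NULL,
                              rows_per_month = 1L,
                              monthly_inflation = 0.005,
                              price_noise_cv = 0.1,
                              contamination_fraction = 0.15) {
  if (!is_month(window_start) || !is_month(window_end) ||
      month_index(window_start) >= month_index(window_end)) {
    abort("window must be two ordered 'YYYY-MM' months")
  }
  if (!is_month(reference_month)) abort("reference_month must be 'YYYY-MM'")
  if (!setequal(names(category_multipliers), category_levels())) {
    abort("category_multipliers must be named ME, MH, MD, OI")
  }
  category_multipliers <- category_multipliers[category_levels()]
  if (abs(min(category_multipliers) - 1) > 1e-12) {
    abort("the minimum category multiplier must be exactly 1")
  }
  if (price_noise_cv < 0) abort("price_noise_cv must be >= 0")
  if (contamination_fraction < 0 || contamination_fraction >= 1) {
    abort("contamination_fraction must be in [0, 1)")
  }
  if (monthly_inflation <= -1) abort("monthly_inflation must exceed -1")
  rows_per_month <- as.integer(rows_per_month)
  if (is.na(rows_per_month) || rows_per_month < 1L) {
    abort("rows_per_month must be a positive integer")
  }
  if (is.null(annual_volume_units)) {
    annual_volume_units <- default_annual_volumes(medicines, window_start,
                                                  window_end)
  }
  if (any(annual_volume_units$units < 0)) abort("volumes must be >= 0")
  bad_code <- setdiff(annual_volume_units$medicine_code,
                      medicines$medicine_code)
  if (length(bad_code)) {
    abort(paste0("volume plan names unknown medicines: ",
                 paste(bad_code, collapse = ", ")))
  }
  structure(
    list(seed = as.integer(seed), window_start = window_start,
         window_end = window_end, reference_month = reference_month,
         medicines = medicines, category_multipliers = category_multipliers,
         annual_volume_units = annual_volume_units,
         rows_per_month = rows_per_month,
         monthly_inflation = monthly_inflation,
         price_noise_cv = price_noise_cv,
         contamination_fraction = contamination_fraction),
    class = "simulation_config")
}

# months of `year` inside the window, as month indices
year_months_in_window <- function(year, lo, hi) {
  m <- month_index(sprintf("%04d-01", year)) + 0:11
  m[m >= lo & m <= hi]
}

# uniform allocation of U units over k slots, remainder to the earliest
allocate_units <- function(units, k) {
  base <- units %/% k
  rep(base, k) + c(rep(1L, units %% k), rep(0L, k - units %% k))
}

#' Generate a synthetic purchase ledger with ground truth
#'
#' Draws one purchase row per medicine x category x month with positive
#' allocated volume, appends the configured share of contamination rows
#' (copies flagged `inactive` or procured by `waiver`/`not_required`), and
#' returns the noise-free closed-form expectations for every downstream
#' pipeline quantity. The same seed yields a byte-identical ledger.
#'
#' @param config A [simulation_config()].
#' @return A list with elements
#'   * `records`: purchase tibble in the ledger CSV schema (eligible rows
#'     first, contamination appended),
#'   * `truth`: per medicine x year x category closed-form expectations
#'     (`volume_mg`, `nominal_expenditure`, `deflated_expenditure`,
#'     `wap_per_mg`, `benchmark_category`, `avoidable_expenditure`,
#'     `additional_mg`, `additional_units`),
#'   * `index`: monthly price-index tibble consistent with the configured
#'     inflation (covers the window and the reference month),
#'   * `master`: medicine master tibble,
#'   * `n_eligible`: number of planted eligible rows.
#' @export
simulate_ledger <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  lo <- month_index(config$window_start)
  hi <- month_index(config$window_end)
  lam <- config$category_multipliers
  r <- config$monthly_inflation
  cv <- config$price_noise_cv

  plan <- config$annual_volume_units %>%
    filter(.data$units > 0) %>%
    mutate(category = factor(.data$category, levels = category_levels())) %>%
    arrange(.data$medicine_code, .data$category, .data$year) %>%
    mutate(category = as.character(.data$category)) %>%
    left_join(select(config$medicines, "medicine_code", "strength_mg",
                     "base_price_per_mg"),
              by = "medicine_code")

  rows <- purrr::pmap(plan, function(medicine_code, category, year, units,
                                     strength_mg, base_price_per_mg) {
    months <- year_months_in_window(year, lo, hi)
    if (!length(months)) return(NULL)
    alloc <- allocate_units(units, length(months))
    # split each month's allocation across the configured number of entities
    k <- config$rows_per_month
    per_row <- unlist(lapply(alloc, allocate_units, k = k))
    month_rep <- rep(months, each = k)
    entity <- rep(sprintf("%s-%02d", category, seq_len(k)), length(months))
    keep <- per_row > 0
    clean <- strength_mg * base_price_per_mg * lam[[category]] *
      (1 + r)^(month_rep[keep] - lo)
    tibble(medicine_code = medicine_code,
           purchase_date = month_from_index(month_rep[keep]),
           category = category,
           entity_id = entity[keep],
           quantity_units = per_row[keep],
           price_clean = clean)
  })
  eligible <- bind_rows(rows)

  withr::with_seed(config$seed, {
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      noise <- exp(rnorm(nrow(eligible), mean = -sdlog^2 / 2, sd = sdlog))
    } else {
      noise <- rep(1, nrow(eligible))
    }
    eligible <- eligible %>%
      mutate(unit_price = .data$price_clean * noise,
             procurement_type = "competitive",
             status = "active") %>%
      select(all_of(purchases_header))

    n_elig <- nrow(eligible)
    f <- config$contamination_fraction
    n_cont <- round(f / (1 - f) * n_elig)
    if (n_cont > 0) {
      pick <- sample.int(n_elig, n_cont, replace = TRUE)
      kinds <- sample(c("inactive", "waiver", "not_required"), n_cont,
                      replace = TRUE)
      cont <- eligible[pick, ] %>%
        mutate(entity_id = paste0(.data$category, "-99"),
               status = ifelse(kinds == "inactive", "inactive", .data$status),
               procurement_type = ifelse(kinds == "inactive",
                                         .data$procurement_type, kinds))
      ledger <- bind_rows(eligible, cont)
    } else {
      ledger <- eligible
    }
  })

  ref <- month_index(config$reference_month)
  idx_hi <- max(hi, ref)
  index <- tibble(month = month_from_index(seq(lo, idx_hi)),
                  index_value = 100 * (1 + r)^(seq(lo, idx_hi) - lo))

  truth <- simulation_truth(config)

  list(records = ledger, truth = truth, index = index,
       master = select(config$medicines, all_of(master_header)),
       n_eligible = nrow(eligible))
}

# noise-free closed forms for every stratum of the volume plan
simulation_truth <- function(config) {
  lo <- month_index(config$window_start)
  hi <- month_index(config$window_end)
  ref <- month_index(config$reference_month)
  lam <- config$category_multipliers
  r <- config$monthly_inflation
  bench_cat <- category_levels()[which.min(lam[category_levels()])]

  config$annual_volume_units %>%
    filter(.data$units > 0) %>%
    left_join(select(config$medicines, "medicine_code", "strength_mg",
                     "base_price_per_mg"),
              by = "medicine_code") %>%
    mutate(
      volume_mg = .data$units * .data$strength_mg,
      nominal_expenditure = purrr::pmap_dbl(
        list(.data$year, .data$units, .data$strength_mg,
             .data$base_price_per_mg, lam[.data$category]),
        function(year, units, strength, base, l) {
          months <- year_months_in_window(year, lo, hi)
          alloc <- allocate_units(units, length(months))
          sum(alloc * strength * base * l * (1 + r)^(months - lo))
        }),
      wap_per_mg = .data$base_price_per_mg *
        as.numeric(lam[.data$category]) * (1 + r)^(ref - lo),
      deflated_expenditure = .data$volume_mg * .data$wap_per_mg,
      benchmark_category = bench_cat,
      benchmark_wap = .data$base_price_per_mg * (1 + r)^(ref - lo),
      avoidable_expenditure = ifelse(
        .data$category == bench_cat, NA_real_,
        .data$volume_mg * (.data$wap_per_mg - .data$benchmark_wap)),
      additional_mg = .data$avoidable_expenditure / .data$benchmark_wap,
      additional_units = as.integer(
        round_half_away(.data$additional_mg / .data$strength_mg))
    ) %>%
    mutate(category = factor(.data$category, levels = category_levels())) %>%
    arrange(.data$medicine_code, .data$year, .data$category) %>%
    mutate(category = as.character(.data$category)) %>%
    select("medicine_code", "year", "category", "units", "volume_mg",
           "nominal_expenditure", "deflated_expenditure", "wap_per_mg",
           "benchmark_category", "benchmark_wap", "avoidable_expenditure",
           "additional_mg", "additional_units")
}

extdata_file <- function(name) {
  path <- system.file("extdata", name, package = "pharmaproc",
                      mustWork = FALSE)
  if (!nzchar(path)) abort(paste0("packaged fixture not found: ", name))
  path
}

#' Packaged published-table fixtures
#'
#' The package ships, as plain CSV fixtures, the published whole-window
#' reconciliation tables of the Brazilian breast-cancer antineoplastic
#' procurement study the pipeline is modelled on: per medicine x purchaser
#' category milligram volumes (`fixture_table1()`), inflation-adjusted
#' spending (`fixture_table2()`), and the per-year avoidable expenditure,
#' additional purchasable units and benchmark category
#' (`fixture_table3()`), together with the ten-medicine master list
#' (`fixture_master()`). Monetary cells are rounded to whole currency units
#' as published, so sums reconcile with published totals only up to small
#' rounding slack.
#'
#' @param complete For `fixture_table3()`: if `TRUE`, expand to the full
#'   medicine x year x category grid with `NA` cells (the published layout);
#'   if `FALSE` (default), return only the non-`NA` cells.
#' @return A tibble.
#' @export
fixture_table1 <- function() {
  readr::read_csv(extdata_file("table1_volume_mg.csv"),
                  col_types = "ccd", show_col_types = FALSE)
}

#' @rdname fixture_table1
#' @export
fixture_table2 <- function() {
  readr::read_csv(extdata_file("table2_spending.csv"),
                  col_types = "ccd", show_col_types = FALSE)
}

#' @rdname fixture_table1
#' @export
fixture_table3 <- function(complete = FALSE) {
  t3 <- readr::read_csv(extdata_file("table3_avoidable.csv"),
                        col_types = "ccidic", show_col_types = FALSE)
  if (!complete) return(t3)
  grid <- tidyr::expand_grid(category = category_levels(),
                             medicine_code = unique(t3$medicine_code),
                             year = 2013:2019)
  left_join(grid, t3, by = c("category", "medicine_code", "year"))
}

#' @rdname fixture_table1
#' @export
fixture_master <- function() {
  read_medicine_master(extdata_file("medicine_master.csv"))
}

#' Write the packaged fixtures to a directory
#'
#' Emits the published-table fixtures and the medicine master list as CSVs in
#' the pipeline's output schemas. Re-running produces byte-identical files.
#'
#' @param out_dir Output directory (created if missing).
#' @return Character vector of the written file paths, invisibly.
#' @export
write_fixtures <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("table1_volume.csv", "table2_spending.csv",
                                "table3_avoidable.csv",
                                "medicine_master.csv"))
  readr::write_csv(fixture_table1(), paths[1])
  readr::write_csv(fixture_table2(), paths[2])
  readr::write_csv(fixture_table3(complete = TRUE), paths[3], na = "NA")
  readr::write_csv(fixture_master(), paths[4])
  invisible(paths)
}
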