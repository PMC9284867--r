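# In-code fixtures shared across test files: a tiny hand-checkable master and
# ledger, plus writers for the CSV schemas.

demo_master <- function() {
  tibble::tibble(
    medicine_code = c("tam", "tra", "pac"),
    name = c("Tamoxifen", "Trastuzumab", "Paclitaxel"),
    strength_mg = c(20, 440, 6),
    dosage_form = c("tablet", "ampoule", "ampoule")
  )
}

demo_record <- function(code = "tam", date = "2015-03", category = "ME",
                        qty = 10L, price = 2,
                        type = "competitive", status = "active",
                        entity = "E1") {
  tibble::tibble(medicine_code = code, purchase_date = date,
                 category = category, entity_id = entity,
                 quantity_units = as.integer(qty), unit_price = price,
                 procurement_type = type, status = status)
}

demo_ledger <- function() {
  dplyr::bind_rows(
    demo_record("tam", "2013-02", "ME", 10L, 2),
    demo_record("tam", "2013-07", "MH", 50L, 1.5),
    demo_record("tra", "2014-11", "OI", 3L, 9000),
    demo_record("pac", "2015-06", "MD", 40L, 30),
    demo_record("pac", "2015-06", "MD", 40L, 50)
  )
}

# flat index: deflation is a no-op
constant_index <- function(from = "2013-01", to = "2019-12", value = 100) {
  tibble::tibble(month = month_seq(from, to), index_value = value)
}

geometric_index <- function(from = "2013-01", to = "2019-12", rate = 0.005) {
  months <- month_seq(from, to)
  tibble::tibble(month = months,
                 index_value = 100 * (1 + rate)^(seq_along(months) - 1))
}

write_ledger_csv <- function(records, dir = withr::local_tempdir(),
                             name = "purchases.csv") {
  path <- file.path(dir, name)
  readr::write_csv(records, path)
  path
}

write_master_csv <- function(master = demo_master(),
                             dir = withr::local_tempdir(),
                             name = "master.csv") {
  path <- file.path(dir, name)
  readr::write_csv(master, path)
  path
}

# small noise-free simulation used by several files
quiet_sim <- function(seed = 11, ...) {
  simulate_ledger(simulation_config(seed = seed, price_noise_cv = 0,
                                    contamination_fraction = 0, ...))
}
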