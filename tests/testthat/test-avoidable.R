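strata_row <- function(code, year, category, volume, wap) {
  tibble::tibble(medicine_code = code, year = year, category = category,
                 volume_mg = volume, expenditure = volume * wap,
                 wap_per_mg = wap)
}

test_that("the benchmark is the cheapest purchasing category of the year", {
  agg <- dplyr::bind_rows(strata_row("tam", 2015L, "ME", 100, 0.12),
                          strata_row("tam", 2015L, "MH", 100, 0.10),
                          strata_row("tam", 2015L, "MD", 100, 0.15))
  b <- benchmark_wap(agg)
  expect_equal(b$benchmark_wap, 0.10)
  expect_equal(b$benchmark_category, "MH")
  # a single purchasing category is its own benchmark
  solo <- benchmark_wap(strata_row("tra", 2016L, "OI", 10, 5))
  expect_equal(solo$benchmark_category, "OI")
  expect_equal(solo$benchmark_wap, 5)
})

test_that("exact benchmark ties break on the fixed category order, with warning", {
  agg <- dplyr::bind_rows(strata_row("tam", 2015L, "OI", 100, 0.10),
                          strata_row("tam", 2015L, "MD", 100, 0.10),
                          strata_row("tam", 2015L, "ME", 50, 0.20))
  expect_warning(b <- benchmark_wap(agg), "tie broken")
  expect_equal(b$benchmark_category, "MD")  # MD precedes OI in ME<MH<MD<OI
})

test_that("avoidable expenditure is actual minus counterfactual, NA at the benchmark", {
  agg <- dplyr::bind_rows(strata_row("tam", 2015L, "ME", 50, 2),
                          strata_row("tam", 2015L, "MH", 80, 1))
  av <- avoidable_expenditure(agg, demo_master())
  me <- av[av$category == "ME", ]
  expect_equal(me$actual_expenditure, 100)
  expect_equal(me$counterfactual_expenditure, 50)
  expect_equal(me$avoidable_expenditure, 50)
  expect_equal(me$benchmark_category, "MH")
  # the benchmark category's own cell is NA by convention
  expect_true(is.na(av$avoidable_expenditure[av$category == "MH"]))
  expect_true(all(av$benchmark_wap <= av$actual_wap + 1e-12))
})

test_that("additional quantity converts money into mg and rounded units", {
  q <- additional_quantity(50, 1, 10)
  expect_equal(q$additional_mg, 50)
  expect_equal(q$additional_units, 5L)
  expect_equal(additional_quantity(0, 2, 10)$additional_units, 0L)
  # halves round away from zero: 25 mg at 10 mg/unit -> 3 units
  expect_equal(additional_quantity(25, 1, 10)$additional_units, 3L)
  expect_true(is.na(additional_quantity(NA_real_, 1, 10)$additional_units))
})

test_that("avoidable expenditure is homogeneous of degree one in prices", {
  agg <- dplyr::bind_rows(strata_row("tam", 2015L, "ME", 50, 2),
                          strata_row("tam", 2015L, "MH", 80, 1),
                          strata_row("tam", 2015L, "OI", 10, 3))
  scaled <- dplyr::mutate(agg, wap_per_mg = wap_per_mg * 7,
                          expenditure = expenditure * 7)
  a1 <- avoidable_expenditure(agg, demo_master())
  a7 <- avoidable_expenditure(scaled, demo_master())
  expect_equal(a7$avoidable_expenditure, 7 * a1$avoidable_expenditure)
  expect_equal(a7$additional_mg, a1$additional_mg)  # mg are scale-free
})

test_that("planted category multipliers are recovered from a clean ledger", {
  lam <- c(ME = 1, MH = 1.2, MD = 1.5, OI = 2)
  meds <- tibble::tibble(medicine_code = "m", name = "M", strength_mg = 10,
                         dosage_form = "tablet", base_price_per_mg = 0.8,
                         annual_units = 1200, inclusion_years = NA_integer_)
  vols <- tidyr::expand_grid(medicine_code = "m",
                             category = c("ME", "MH", "MD", "OI"),
                             year = 2013:2019) |>
    dplyr::mutate(units = 1200L)  # equal volumes V across categories
  cfg <- simulation_config(seed = 2, medicines = meds,
                           category_multipliers = lam,
                           annual_volume_units = vols,
                           monthly_inflation = 0, price_noise_cv = 0,
                           contamination_fraction = 0)
  sim <- simulate_ledger(cfg)
  defl <- adjust_records(sim$records, sim$index, cfg$reference_month)
  av <- avoidable_expenditure(aggregate_strata(defl, sim$master), sim$master)
  expect_true(all(av$benchmark_category == "ME"))
  v_mg <- 1200 * 10
  for (cat in c("MH", "MD", "OI")) {
    got <- av$avoidable_expenditure[av$category == cat]
    expect_equal(got, rep(v_mg * 0.8 * (lam[[cat]] - 1), 7),
                 tolerance = 1e-6)
  }
  expect_true(all(av$avoidable_expenditure >= 0, na.rm = TRUE))
})

test_that("additional units equal to purchases give a 100% share", {
  av <- tibble::tibble(medicine_code = "tam", additional_units = 500L)
  totals <- tibble::tibble(medicine_code = "tam", volume_mg = 500 * 20)
  s <- additional_share(av, totals, demo_master())
  expect_equal(s$additional_share, 100)
  expect_equal(s$purchased_units, 500)
})
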