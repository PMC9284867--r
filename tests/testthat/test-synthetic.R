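test_that("the generator is deterministic in the seed and seeds differ", {
  cfg <- simulation_config(seed = 31)
  a <- simulate_ledger(cfg)
  b <- simulate_ledger(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  dir <- withr::local_tempdir()
  write_purchases(a$records, file.path(dir, "a.csv"))
  write_purchases(b$records, file.path(dir, "b.csv"))
  expect_identical(readBin(file.path(dir, "a.csv"), "raw", 1e6),
                   readBin(file.path(dir, "b.csv"), "raw", 1e6))
  other <- simulate_ledger(simulation_config(seed = 32))
  expect_false(identical(a$records, other$records))
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(category_multipliers =
                                   c(ME = 1.1, MH = 1.2, MD = 1.5, OI = 2)),
               "minimum category multiplier")
  expect_error(simulation_config(price_noise_cv = -0.1), "price_noise_cv")
  expect_error(simulation_config(contamination_fraction = 1), "contamination")
  expect_error(simulation_config(window_start = "2019-12",
                                 window_end = "2013-01"), "ordered")
})

test_that("noise-free generation matches closed-form truth to 1e-9", {
  sim <- quiet_sim(seed = 77)
  defl <- adjust_records(sim$records, sim$index, "2019-07")
  agg <- aggregate_strata(defl, sim$master)
  cmp <- dplyr::inner_join(agg, sim$truth,
                           by = c("medicine_code", "year", "category"),
                           suffix = c("_got", "_true"))
  expect_equal(nrow(cmp), nrow(sim$truth))
  expect_equal(cmp$volume_mg_got, cmp$volume_mg_true)
  expect_equal(cmp$expenditure, cmp$deflated_expenditure, tolerance = 1e-9)
  expect_equal(cmp$wap_per_mg_got, cmp$wap_per_mg_true, tolerance = 1e-9)
  # nominal (undeflated) expenditure also matches its closed form
  nom <- aggregate_strata(sim$records, sim$master)
  cmp2 <- dplyr::inner_join(nom, sim$truth,
                            by = c("medicine_code", "year", "category"))
  expect_equal(cmp2$expenditure, cmp2$nominal_expenditure, tolerance = 1e-9)
})

test_that("two multipliers with equal volumes give the textbook avoidable spend", {
  meds <- tibble::tibble(medicine_code = "m", name = "M", strength_mg = 5,
                         dosage_form = "ampoule", base_price_per_mg = 2,
                         annual_units = 100, inclusion_years = NA_integer_)
  vols <- tidyr::expand_grid(medicine_code = "m", category = c("ME", "MH"),
                             year = 2013:2019) |>
    dplyr::mutate(units = 100L)
  cfg <- simulation_config(
    seed = 1, medicines = meds,
    category_multipliers = c(ME = 1, MH = 2, MD = 1, OI = 1),
    annual_volume_units = vols, monthly_inflation = 0,
    price_noise_cv = 0, contamination_fraction = 0)
  sim <- simulate_ledger(cfg)
  defl <- adjust_records(sim$records, sim$index, cfg$reference_month)
  av <- avoidable_expenditure(aggregate_strata(defl, sim$master), sim$master)
  v_mg <- 100 * 5
  got <- av$avoidable_expenditure[av$category == "MH"]
  expect_equal(got, rep(v_mg * 2, 7), tolerance = 1e-12)  # V x base_price
  expect_equal(sim$truth$avoidable_expenditure[sim$truth$category == "MH"],
               rep(v_mg * 2, 7))
})

test_that("truth is internally consistent with the avoidable formulas", {
  tr <- quiet_sim(seed = 15)$truth
  expect_equal(tr$deflated_expenditure, tr$volume_mg * tr$wap_per_mg)
  non_na <- !is.na(tr$avoidable_expenditure)
  expect_equal(tr$avoidable_expenditure[non_na],
               (tr$volume_mg * (tr$wap_per_mg - tr$benchmark_wap))[non_na])
  expect_true(all(tr$avoidable_expenditure[non_na] >= 0))
  expect_true(all(is.na(tr$avoidable_expenditure) ==
                    (tr$category == tr$benchmark_category)))
})

test_that("packaged fixtures load, reconcile and re-emit byte-identically", {
  t1 <- fixture_table1()
  t3 <- fixture_table3()
  expect_equal(dplyr::n_distinct(t1$medicine_code), 10L)
  expect_setequal(unique(t3$category), c("ME", "MH", "MD", "OI"))
  full <- fixture_table3(complete = TRUE)
  expect_equal(nrow(full), 4 * 10 * 7)
  expect_true(anyNA(full$avoidable_expenditure))
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- write_fixtures(dir1)
  p2 <- write_fixtures(dir2)
  for (i in seq_along(p1)) {
    expect_identical(readBin(p1[i], "raw", 1e6), readBin(p2[i], "raw", 1e6))
  }
})
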