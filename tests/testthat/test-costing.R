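test_that("equivalent annual cost follows the annuity-due convention", {
  expect_equal(equivalent_annual_cost(2901.14, 5, 0.05), 638.18,
               tolerance = 0.02 / 638)
  expect_equal(equivalent_annual_cost(7 * 90.50, 5, 0.05), 139.35,
               tolerance = 0.02 / 139)
  expect_identical(equivalent_annual_cost(0, 5, 0.05), 0)
  expect_equal(equivalent_annual_cost(1000, 5, 0), 200)
  expect_error(equivalent_annual_cost(-1), "non-negative")
})

test_that("EAC is decreasing in lifetime and increasing in rate", {
  lifetimes <- 1:20
  eac_by_life <- equivalent_annual_cost(1000, lifetimes, 0.05)
  expect_true(all(diff(eac_by_life) < 0))
  rates <- seq(0, 0.15, by = 0.01)
  eac_by_rate <- equivalent_annual_cost(1000, 5, rates)
  expect_true(all(diff(eac_by_rate) > 0))
})

test_that("the programme ledger reproduces the published cost accounting", {
  led <- read_ledger(ledger_path("programme"))
  cb <- compute_ledger(led, population_size = 30000L)

  # capital rows, annuitised
  cap <- cb$items[cb$items$category == "capital", ]
  printed_cap <- c("Coordinator's furnishings" = 638.17,
                   "Offices' furnishings" = 492.49,
                   "Sphygmomanometer" = 139.36,
                   "Coordinator's computers" = 1874.16,
                   "Offices' computers" = 1574.29)
  for (nm in names(printed_cap))
    expect_equal(cap$annual_cost[cap$item == nm], printed_cap[[nm]],
                 tolerance = 0.002, info = nm)

  # category subtotals within 0.2% of print
  printed_sub <- c(labour = 309241.87, capital = 4718.48, land = 41783.86,
                   resource = 1267.76 + 10711.13 + 73127.78,
                   overhead = 16.07, visit = 95.87, consumption = 235.18)
  for (cat in names(printed_sub)) {
    got <- cb$by_category$annual_cost[cb$by_category$category == cat]
    expect_equal(got, printed_sub[[cat]], tolerance = 0.002, info = cat)
  }

  expect_equal(cb$programme_total, 440850.89, tolerance = 500 / 440851)
  expect_equal(cb$programme_per_patient, 14.70, tolerance = 0.05 / 14.70)
  expect_equal(cb$annual_total_per_patient, 361.81, tolerance = 0.002)
})

test_that("the usual-care ledger reproduces its per-patient totals", {
  cb <- compute_ledger(read_ledger(ledger_path("usual")), 30000L)
  expect_equal(cb$annual_total_per_patient, 295.70, tolerance = 0.002)
  expect_equal(cb$programme_total, 0)  # no institution-level items
})

test_that("compute_ledger handles degenerate and invalid input", {
  empty <- data.frame(item = character(), category = character(),
                      unit_cost = numeric(), quantity = numeric())
  cb <- compute_ledger(empty, 1000L)
  expect_equal(cb$programme_total, 0)
  expect_equal(cb$annual_total_per_patient, 0)
  bad <- data.frame(item = "x", category = "entertainment",
                    unit_cost = 1, quantity = 1)
  expect_error(compute_ledger(bad, 100L), "unknown ledger category")
  expect_error(compute_ledger(empty, 0L), "population_size")
})

test_that("annual treatment cost combines components as specified", {
  usual <- strategy_components(base_case(), "usual")
  expect_equal(annual_treatment_cost(usual),
               206.43 * 0.70 + 29.10 + 7.68 * (9.63 + 1.98) + 17.44,
               tolerance = 1e-9)
  expect_equal(annual_treatment_cost(usual, first_cycle = TRUE) -
                 annual_treatment_cost(usual), 117.78)

  zero <- lapply(usual, function(x) 0)
  expect_equal(annual_treatment_cost(zero), 0)

  # linearity in each component
  for (nm in c("drug_cost_year", "test_cost_year", "programme_fee_year",
               "ambulance_cost_year")) {
    bumped <- usual; bumped[[nm]] <- usual[[nm]] + 10
    slope <- annual_treatment_cost(bumped) - annual_treatment_cost(usual)
    expect_equal(slope, if (nm == "drug_cost_year") 10 * usual$drug_coverage
                 else 10, tolerance = 1e-9, info = nm)
  }
})

test_that("hospital cost is charged only to assisted events", {
  expect_equal(event_episode_cost(TRUE, 10041.65), 10041.65)
  expect_equal(event_episode_cost(FALSE, 10041.65), 0)
  expect_equal(event_episode_cost(TRUE, 0), 0)
})

test_that("lognormal fit recovers generating parameters", {
  set.seed(42)
  draws <- exp(rnorm(1e5, 8.24, 1.39))
  fit <- fit_lognormal(draws)
  expect_equal(fit[["mu"]], 8.24, tolerance = 0.02 / 8.24)
  expect_equal(fit[["sigma"]], 1.39, tolerance = 0.02 / 1.39)

  fit_const <- fit_lognormal(rep(7, 10))
  expect_equal(fit_const[["mu"]], log(7))
  expect_equal(fit_const[["sigma"]], 0)

  expect_error(fit_lognormal(c(1, 0)), "positive")
  expect_error(fit_lognormal(3), "at least 2")
})
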