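test_that("event probability is hazard-ratio scaling with a cap", {
  expect_equal(event_probability(0.0255, 0.6150), 0.0156825)
  expect_equal(event_probability(0.37, 1.0), 0.37)
  expect_equal(event_probability(0.8, 2.0), 1.0)
  expect_error(event_probability(1.2, 1), "\\[0, 1\\]")
  expect_error(event_probability(0.5, 0), "hr")
})

test_that("acute event sub-tree resolves to the published base-case split", {
  out <- acute_event_outcome("65-74", base_aem)
  expect_equal(out[["unassisted_die"]], 0.10 + 0.90 * 0.367 * 0.30)
  expect_equal(out[["assisted_die"]], 0.90 * 0.633 * 0.15)
  expect_equal(out[["assisted_survive"]], 0.484245)
  expect_equal(out[["unassisted_survive"]], 0.23121)
  expect_equal(sum(out), 1)

  old <- acute_event_outcome("75+", base_aem)
  expect_equal(old[["unassisted_die"]], 0.10 + 0.90 * 0.367 * 0.60)
  expect_equal(sum(old), 1)
})

test_that("acute event sub-tree edge cases and random closure", {
  aem <- base_aem
  aem$p_sudden_death <- 1
  expect_equal(acute_event_outcome("65-74", aem)[["unassisted_die"]], 1)

  aem <- base_aem
  aem$p_sudden_death <- 0
  aem[c("cfr_assisted_65_74", "cfr_unassisted_65_74")] <- list(0, 0)
  out <- acute_event_outcome("65-74", aem)
  expect_equal(out[["assisted_die"]] + out[["unassisted_die"]], 0)

  set.seed(11)
  for (i in 1:25) {
    aem <- base_aem
    aem$p_sudden_death <- runif(1)
    aem$p_unrecognized <- runif(1)
    cfr_yes <- runif(1)
    aem$cfr_assisted_75 <- cfr_yes
    aem$cfr_unassisted_75 <- runif(1, cfr_yes, 1)
    expect_equal(sum(acute_event_outcome("75+", aem)), 1, tolerance = 1e-12)
  }
})

test_that("discounting follows the cycle-0-undiscounted convention", {
  expect_equal(discount(100, 0.05, 0), 100)
  expect_equal(discount(100, 0.05, 1), 100 / 1.05)
  expect_equal(discount(42, 0, 17), 42)
})

test_that("one-cycle transition: absorbing death, conservation, rewards", {
  st <- econ_settings()
  dead <- list(occupancy = c(intermediate = 0, high = 0,
                             dead_cv = 0.4, dead_other = 0.6), age = 70)
  out <- cycle_transition(dead, base_case(), "usual", st, default_lt)
  expect_equal(out$state$occupancy, dead$occupancy)
  expect_equal(out$cycle_cost, 0)
  expect_equal(out$cycle_lyg, 0)

  # no events, no background mortality: occupancy unchanged, LYG = live mass
  live <- list(occupancy = c(intermediate = 0.5, high = 0.3,
                             dead_cv = 0.1, dead_other = 0.1), age = 72)
  out2 <- cycle_transition(live, zero_risk_params(), "usual", st,
                           immortal_lt())
  expect_equal(out2$state$occupancy[c("intermediate", "high")],
               live$occupancy[c("intermediate", "high")])
  expect_equal(out2$cycle_lyg, 0.8)
  expect_equal(sum(out2$state$occupancy), 1, tolerance = 1e-12)
  expect_error(cycle_transition(list(occupancy = live$occupancy, age = 100),
                                base_case(), "usual", st, default_lt),
               "horizon")
})

test_that("cohort survives to the horizon when nothing can kill it", {
  res <- run_cohort(zero_risk_params(), "usual",
                    econ_settings(discount_rate = 0), immortal_lt())
  expect_equal(res$disc_lyg, 35)  # ages 65..99, one year per completed cycle
})

test_that("occupancy is conserved in every cycle of a base-case run", {
  for (strat in c("usual", "programme")) {
    res <- run_cohort(base_case(), strat, econ_settings(), default_lt)
    occ_sums <- rowSums(res$trace[c("intermediate", "high",
                                    "dead_cv", "dead_other")])
    expect_true(all(abs(occ_sums - 1) < 1e-12), info = strat)
    expect_true(all(res$trace[c("intermediate", "high")] >= 0))
  }
})

test_that("discounted LYG is monotone in rate, risks, fatality, mortality", {
  p <- base_case()
  lyg_at <- function(params, rate = 0.05, lt = default_lt) {
    run_cohort(params, "usual", econ_settings(discount_rate = rate), lt,
               trace = FALSE)$disc_lyg
  }
  rates <- c(0, 0.03, 0.05, 0.07, 0.12)
  expect_true(all(diff(vapply(rates, function(r) lyg_at(p, r),
                              numeric(1))) < 0))

  riskier <- p
  for (nm in grep("^p_ref", names(p$common), value = TRUE))
    riskier$common[[nm]] <- dist_spec("fixed",
                                      base = min(1, 2 * p$common[[nm]]$base))
  expect_lt(lyg_at(riskier), lyg_at(p))

  deadlier <- p
  for (nm in grep("^cfr", names(p$common), value = TRUE))
    deadlier$common[[nm]] <- dist_spec("fixed",
                                       base = min(1, p$common[[nm]]$base + 0.2))
  expect_lt(lyg_at(deadlier), lyg_at(p))

  heavier <- synthetic_life_table(a = 0.02)
  expect_lt(lyg_at(p, lt = heavier), lyg_at(p))
})

test_that("a lower hazard ratio never yields fewer life-years", {
  set.seed(19)
  for (i in 1:10) {
    drawn <- sample_parameter_set(base_case())
    if (drawn$programme$hr$base >= drawn$usual$hr$base) next
    ru <- run_cohort(drawn, "usual", econ_settings(), default_lt,
                     trace = FALSE)
    rp <- run_cohort(drawn, "programme", econ_settings(), default_lt,
                     trace = FALSE)
    expect_gte(rp$disc_lyg, ru$disc_lyg)
  }
})

test_that("cohort expectations agree with the microsimulation oracle", {
  scenarios <- list(
    list(p = base_case(), strat = "usual", st = econ_settings()),
    list(p = base_case(), strat = "programme", st = econ_settings()),
    list(p = base_case(), strat = "usual",
         st = econ_settings(discount_rate = 0)),
    list(p = base_case(), strat = "programme",
         st = econ_settings(start_age = 75, p_start_intermediate = 0.3)),
    list(p = zero_risk_params(), strat = "usual", st = econ_settings()))
  for (k in seq_along(scenarios)) {
    sc <- scenarios[[k]]
    coh <- run_cohort(sc$p, sc$strat, sc$st, default_lt, trace = FALSE)
    ms <- run_microsim(sc$p, sc$strat, sc$st, default_lt,
                       n_individuals = 60000L, seed = 100 + k)
    expect_lt(abs(ms$disc_lyg - coh$disc_lyg),
              max(3 * ms$se_lyg, 1e-9), label = paste("LYG scenario", k))
    expect_lt(abs(ms$disc_cost - coh$disc_cost),
              max(3 * ms$se_cost, 1e-9), label = paste("cost scenario", k))
  }
})

test_that("microsimulation is reproducible and degenerate cases collapse", {
  a <- run_microsim(base_case(), "usual", econ_settings(), default_lt,
                    n_individuals = 500L, seed = 5)
  b <- run_microsim(base_case(), "usual", econ_settings(), default_lt,
                    n_individuals = 500L, seed = 5)
  expect_identical(a, b)

  # zero risk, immortal background: every path is identical
  z <- run_microsim(zero_risk_params(), "usual",
                    econ_settings(discount_rate = 0), immortal_lt(),
                    n_individuals = 200L, seed = 1)
  expect_equal(z$se_lyg, 0)
  expect_equal(z$disc_lyg, 35)

  one <- run_microsim(base_case(), "usual", econ_settings(), default_lt,
                      n_individuals = 1L, seed = 3)
  expect_equal(one$n, 1L)
})
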