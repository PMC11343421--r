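# Cohort engine: conservation, closed-form limits, accrual arithmetic.

test_that("identity transitions and no mortality leave the cohort in place", {
  p <- degenerate_bundle(horizon = 12)
  for (arm in c("EPG_SOC", "SOC")) {
    tr <- run_cohort(p, arm)
    expect_equal(tr$n_cycles, 12L)
    final_states <- tr$occupancy[13, 1:4] + tr$occupancy[13, 5:8]
    expect_equal(unname(final_states), rep(0.25, 4), tolerance = 1e-10)
    expect_equal(sum(tr$occupancy[13, 9:10]), 0, tolerance = 1e-10)
    s <- accrue_outcomes(tr, p)
    expect_equal(s$undiscounted$ly$total, 1, tolerance = 1e-10)
  }
})

test_that("constant monthly death probability recovers the geometric-series LY", {
  q <- 0.002
  p <- degenerate_bundle(monthly_death_prob = q, horizon = "lifetime",
                         max_age = 400)
  tr <- run_cohort(p, "SOC")
  s <- accrue_outcomes(tr, p)
  expect_equal(s$undiscounted$ly$total, (1 / q) / 12, tolerance = 1e-3)
  # all deaths routed to the CV state (non-CV spec is identical, so the
  # subtraction yields zero and the flat life table adds nothing)
  expect_equal(sum(tr$events$noncv_deaths), 0, tolerance = 1e-12)
  expect_equal(unname(tr$occupancy[tr$n_cycles + 1, "dead_cv"]),
               1 - (1 - q)^tr$n_cycles, tolerance = 1e-9)
})

test_that("occupancy is conserved and dead mass is monotone on the calibrated fixture", {
  p <- calibrated_bundle()
  for (arm in c("EPG_SOC", "SOC")) {
    tr <- run_cohort(p, arm)
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-9), info = arm)
    expect_true(all(tr$occupancy >= -1e-15), info = arm)
    expect_true(all(diff(tr$occupancy[, "dead_cv"]) >= -1e-15), info = arm)
    expect_true(all(diff(tr$occupancy[, "dead_noncv"]) >= -1e-15), info = arm)
  }
  # comparator arm never holds on-treatment mass
  tr_soc <- run_cohort(p, "SOC")
  expect_equal(max(tr_soc$occupancy[, 1:4]), 0)
})

test_that("discount factors follow (1 + r)^(-cycle/12)", {
  expect_equal(discount_factor(0, 0:120), rep(1, 121))
  expect_equal(discount_factor(0.03, 12), 1 / 1.03, tolerance = 1e-12)
  expect_equal(discount_factor(0.03, 6), 1.03^-0.5, tolerance = 1e-12)
  expect_equal(discount_factor(0.03, 0), 1)
  expect_error(discount_factor(-0.01, 1))
})

test_that("expected hHF events follow the log-linear rate model", {
  m <- event_rate_model(intercept = log(0.007),
                        state_coefs = c(Q1 = log(1.5), Q2 = 0, Q3 = 0))
  occ <- c(Q1 = 1, Q2 = 0, Q3 = 0, Q4 = 0)
  expect_equal(expected_hhf_events(m, occ, on_treatment = 0), 0.0105,
               tolerance = 1e-12)
  expect_equal(expected_hhf_events(m, occ * 0, on_treatment = 0), 0)
  # null treatment effect: both statuses give identical expectations
  expect_equal(expected_hhf_events(m, occ, 1), expected_hhf_events(m, occ, 0))
})

test_that("accrual prices a patient-cycle and an event as published", {
  p <- degenerate_bundle(horizon = 1)
  occ <- matrix(0, 2, 10,
                dimnames = list(NULL, c(paste0(QSTATES, "_on"),
                                        paste0(QSTATES, "_off"),
                                        "dead_cv", "dead_noncv")))
  occ[, "Q1_off"] <- 1   # one full cycle in the worst quartile
  mk_trace <- function(hhf) {
    structure(list(occupancy = occ,
                   events = data.frame(cycle = 0L, hhf = hhf, cv_deaths = 0,
                                       noncv_deaths = 0, discontinuations = 0,
                                       age = 64.6),
                   arm = "SOC", n_cycles = 1L, starting_age = 64.6,
                   cycle_length = 1),
              class = "cohort_trace")
  }
  s <- accrue_outcomes(mk_trace(0), p)
  expect_equal(s$undiscounted$qaly$total, 0.613 / 12, tolerance = 1e-12)
  expect_equal(s$undiscounted$ly$total, 1 / 12, tolerance = 1e-12)

  # one expected hospitalisation at cycle 0: a full 0.335 QALY loss and the
  # admission cost, plus the state-based accruals above
  s1 <- accrue_outcomes(mk_trace(1), p)
  expect_equal(s1$undiscounted$qaly$loss_hhf, -0.335, tolerance = 1e-12)
  expect_equal(s1$undiscounted$cost$hhf, 5276, tolerance = 1e-12)
  expect_equal(s1$undiscounted$qaly$total, 0.613 / 12 - 0.335,
               tolerance = 1e-12)
})

test_that("costs are homogeneous of degree one in cost inputs", {
  p <- calibrated_bundle()
  doubled <- p
  doubled$costs$monthly_drug_cost <- doubled$costs$monthly_drug_cost * 2
  for (f in c("hhf_cost", "cv_death_cost", "noncv_death_cost",
              "monthly_disease_mgmt_cost")) {
    doubled$costs[[f]] <- doubled$costs[[f]] * 2
  }
  doubled$adverse_events$unit_cost <- doubled$adverse_events$unit_cost * 2
  a <- accrue_outcomes(run_cohort(p, "EPG_SOC"), p)
  b <- accrue_outcomes(run_cohort(doubled, "EPG_SOC"), doubled)
  for (blk in c("discounted", "undiscounted")) {
    for (f in c("total", "drug", "hhf", "cv_death", "ae", "disease_mgmt")) {
      expect_equal(b[[blk]]$cost[[f]], 2 * a[[blk]]$cost[[f]],
                   tolerance = 1e-12)
    }
  }
  # QALYs untouched by cost scaling
  expect_equal(b$discounted$qaly$total, a$discounted$qaly$total)
})

test_that("cost categories sum to the total and QALY <= LY", {
  p <- calibrated_bundle()
  for (arm in c("EPG_SOC", "SOC")) {
    s <- accrue_outcomes(run_cohort(p, arm), p)
    for (blk in c("discounted", "undiscounted")) {
      cc <- s[[blk]]$cost
      expect_equal(cc$drug + cc$hhf + cc$cv_death + cc$noncv_death + cc$ae +
                     cc$disease_mgmt, cc$total, tolerance = 1e-9)
      expect_lt(s[[blk]]$qaly$total, s[[blk]]$ly$total)
    }
    expect_lte(s$discounted$ly$total, s$undiscounted$ly$total)
    expect_lte(s$discounted$cost$total, s$undiscounted$cost$total)
  }
})

test_that("zero discount rates reproduce undiscounted totals exactly", {
  p <- calibrated_bundle()
  p$economics$annual_discount_rate_cost <- 0
  p$economics$annual_discount_rate_benefit <- 0
  s <- accrue_outcomes(run_cohort(p, "EPG_SOC"), p)
  expect_identical(s$discounted$ly$total, s$undiscounted$ly$total)
  expect_identical(s$discounted$qaly$total, s$undiscounted$qaly$total)
  expect_identical(s$discounted$cost$total, s$undiscounted$cost$total)
})

test_that("half-cycle-corrected LY lies between start- and end-of-cycle sums", {
  p <- calibrated_bundle()
  tr <- run_cohort(p, "SOC")
  n <- tr$n_cycles
  alive <- rowSums(tr$occupancy[, 1:8])
  ly_start <- sum(alive[1:n]) / 12
  ly_end <- sum(alive[2:(n + 1)]) / 12
  s <- accrue_outcomes(tr, p)
  expect_gt(s$undiscounted$ly$total, ly_end)
  expect_lt(s$undiscounted$ly$total, ly_start)
  expect_equal(s$undiscounted$ly$total, (ly_start + ly_end) / 2,
               tolerance = 1e-12)
})

test_that("mean time on treatment covers the boundary and geometric cases", {
  # no discontinuation, no death, 24-month horizon -> exactly 2 years
  p <- degenerate_bundle(horizon = 24)
  expect_equal(mean_time_on_treatment(run_cohort(p, "EPG_SOC")), 2,
               tolerance = 1e-9)
  expect_equal(mean_time_on_treatment(run_cohort(p, "SOC")), 0)

  # constant monthly discontinuation d -> about (1/d)/12 years over a long
  # horizon (half-cycle correction and truncation keep it just below)
  d <- 0.002
  pd <- degenerate_bundle(disc_prob = d, horizon = "lifetime", max_age = 400)
  yrs <- mean_time_on_treatment(run_cohort(pd, "EPG_SOC"))
  expect_equal(yrs, (1 / d) / 12, tolerance = 2e-3)
})

test_that("horizon is clamped with a warning when the life table runs out", {
  p <- degenerate_bundle(horizon = "lifetime", max_age = 300)
  p$life_table <- flat_life_table(max_age = 120)
  p$economics$max_age <- 300
  expect_warning(tr <- run_cohort(p, "SOC"), "clamped")
  expect_lte(tr$n_cycles, (121 - 64.6) * 12)
})
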