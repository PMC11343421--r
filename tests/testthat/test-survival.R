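# Family parameterisations checked against closed forms and reduction
# identities; per-cycle probabilities against telescoping reconstruction.

all_family_specs <- function() {
  list(
    exponential = survival_spec("exponential", c(intercept = log(0.05))),
    weibull = survival_spec("weibull", c(intercept = log(30)),
                            list(sigma = 0.8)),
    lognormal = survival_spec("lognormal", c(intercept = log(40)),
                              list(sigma = 1.1)),
    loglogistic = survival_spec("loglogistic", c(intercept = log(35)),
                                list(sigma = 0.9)),
    gompertz = survival_spec("gompertz", c(intercept = log(0.01)),
                             list(shape = 0.02)),
    gengamma = survival_spec("gengamma", c(intercept = log(45)),
                             list(sigma = 1.2, Q = 0.7))
  )
}

test_that("S(0) = 1 and S is non-increasing for every family", {
  grid <- seq(0, 240, by = 1)
  for (sp in all_family_specs()) {
    s <- survival_probability(sp, grid)
    expect_equal(s[1], 1, info = sp$family)
    expect_true(all(diff(s) <= 1e-12), info = sp$family)
    # hazard -d/dt log S >= 0 on the grid
    expect_true(all(diff(log(pmax(s, 1e-300))) <= 1e-12), info = sp$family)
  }
  expect_error(survival_probability(all_family_specs()$weibull, -1), ">= 0")
})

test_that("exponential closed form and Weibull shape-1 reduction hold", {
  ex <- survival_spec("exponential", c(intercept = log(0.1)))
  expect_equal(survival_probability(ex, 12), exp(-1.2), tolerance = 1e-12)

  # Weibull with sigma = 1 and scale 1/rate is exponential(rate)
  ex05 <- survival_spec("exponential", c(intercept = log(0.05)))
  wb <- survival_spec("weibull", c(intercept = log(1 / 0.05)),
                      list(sigma = 1))
  for (t in c(1, 6, 24)) {
    expect_equal(survival_probability(wb, t), survival_probability(ex05, t),
                 tolerance = 1e-12)
  }
})

test_that("generalised gamma nests Weibull (Q = 1) and lognormal (Q = 0)", {
  gg1 <- survival_spec("gengamma", c(intercept = log(30)),
                       list(sigma = 0.8, Q = 1))
  wb <- survival_spec("weibull", c(intercept = log(30)), list(sigma = 0.8))
  gg0 <- survival_spec("gengamma", c(intercept = log(30)),
                       list(sigma = 0.8, Q = 0))
  ln <- survival_spec("lognormal", c(intercept = log(30)), list(sigma = 0.8))
  t <- c(0.5, 3, 12, 60, 180)
  expect_equal(survival_probability(gg1, t), survival_probability(wb, t),
               tolerance = 1e-12)
  expect_equal(survival_probability(gg0, t), survival_probability(ln, t),
               tolerance = 1e-10)
  # near-zero Q approaches the lognormal limit
  ggq <- survival_spec("gengamma", c(intercept = log(30)),
                       list(sigma = 0.8, Q = 1e-5))
  expect_equal(survival_probability(ggq, t), survival_probability(ln, t),
               tolerance = 1e-4)
})

test_that("covariates act on the family's canonical scale", {
  # AFT: positive coefficient lengthens survival times
  wb <- survival_spec("weibull",
                      c(intercept = log(30), treatment = 0.3, Q1 = -0.5),
                      list(sigma = 0.8))
  expect_gt(survival_probability(wb, 24, treatment = 1),
            survival_probability(wb, 24, treatment = 0))
  expect_lt(survival_probability(wb, 24, state = "Q1"),
            survival_probability(wb, 24, state = "Q4"))
  # AFT treatment effect equals a time rescaling by exp(beta)
  expect_equal(survival_probability(wb, 24 * exp(0.3), treatment = 1),
               survival_probability(wb, 24, treatment = 0), tolerance = 1e-12)
  # PH: positive coefficient raises the hazard proportionally
  ex <- survival_spec("exponential", c(intercept = log(0.02), treatment = 0.4))
  expect_equal(log(survival_probability(ex, 10, treatment = 1)) /
                 log(survival_probability(ex, 10, treatment = 0)),
               exp(0.4), tolerance = 1e-12)
})

test_that("per-cycle probabilities: memorylessness, monotone hazards, bounds", {
  # zero hazard -> zero probability
  p0 <- cycle_event_probability(near_zero_hazard(), hazard_context(0))
  expect_lt(p0, 1e-12)

  # exponential: 1 - exp(-lambda * delta), independent of elapsed time
  ex <- survival_spec("exponential", c(intercept = log(0.08)))
  for (t in c(0, 7.3, 100)) {
    expect_equal(cycle_event_probability(ex, hazard_context(t)),
                 1 - exp(-0.08), tolerance = 1e-12)
  }

  # increasing-hazard Weibull: later cycles are riskier
  wb <- survival_spec("weibull", c(intercept = log(60)), list(sigma = 0.5))
  p1 <- cycle_event_probability(wb, hazard_context(6))
  p2 <- cycle_event_probability(wb, hazard_context(30))
  expect_gt(p2, p1)

  for (sp in all_family_specs()) {
    p <- cycle_event_probability(sp, hazard_context(0:119))
    expect_true(all(p >= 0 & p <= 1), info = sp$family)
  }
})

test_that("cycle probabilities telescope back to the survivor function", {
  # product of per-cycle survival over any partition reconstructs S(T)/S(0)
  for (sp in all_family_specs()) {
    for (step in c(1, 3)) {
      starts <- seq(0, 60 - step, by = step)
      p <- cycle_event_probability(
        sp, hazard_context(starts, cycle_length = step))
      expect_equal(prod(1 - p), survival_probability(sp, 60),
                   tolerance = 1e-10, info = sp$family)
    }
  }
})

test_that("life-table non-CV probability follows the stated arithmetic", {
  lt <- flat_life_table(qx = 0.012, cv_share = 0.5)
  expect_equal(noncv_lifetable_probability(lt, 70),
               1 - (1 - 0.012 * 0.5)^(1 / 12), tolerance = 1e-12)
  # equal rates in both sexes: the mix is irrelevant
  expect_equal(noncv_lifetable_probability(lt, 70, c(male = 0.9, female = 0.1)),
               noncv_lifetable_probability(lt, 70, c(male = 0.1, female = 0.9)))
  # all deaths cardiovascular -> no background non-CV mortality
  lt_cv <- flat_life_table(qx = 0.02, cv_share = 1)
  expect_equal(noncv_lifetable_probability(lt_cv, 80), 0)
  expect_error(noncv_lifetable_probability(lt, 500), "outside life-table range")
})

test_that("non-CV blending takes the maximum and subtraction floors at zero", {
  expect_equal(blended_noncv_probability(0.001, 0.003), 0.003)
  expect_equal(blended_noncv_probability(0.004, 0.003), 0.004)
  expect_equal(blended_noncv_probability(0.002, 0.002), 0.002)

  ac <- survival_spec("exponential", c(intercept = log(0.010)))
  cv <- survival_spec("exponential", c(intercept = log(0.004)))
  ctx <- hazard_context(0)
  expect_equal(trial_noncv_probability(ac, cv, ctx),
               (1 - exp(-0.010)) - (1 - exp(-0.004)), tolerance = 1e-12)
  expect_equal(trial_noncv_probability(ac, ac, ctx), 0)
  # crossing curves: CV exceeds all-cause -> clipped at zero with a warning
  expect_warning(p <- trial_noncv_probability(cv, ac, ctx), "clipped")
  expect_equal(p, 0)
})
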