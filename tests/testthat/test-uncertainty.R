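# Sensitivity-analysis machinery: tornado, PSA, scenarios.

test_that("a zero-width DSA bar reproduces the base ICER twice", {
  p <- calibrated_bundle()
  base <- run_base_case(p)$incremental$icer_per_qaly
  tab <- run_dsa(p, list(dsa_spec("costs.hhf_cost", p$costs$hhf_cost,
                                  p$costs$hhf_cost)))
  expect_equal(tab$icer_low, base, tolerance = 1e-9)
  expect_equal(tab$icer_high, base, tolerance = 1e-9)
  expect_equal(tab$width, 0)
  expect_equal(attr(tab, "base_icer"), base)
})

test_that("the ICER increases in drug cost and when the CV benefit is removed", {
  p <- calibrated_bundle()
  base <- run_base_case(p)$incremental$icer_per_qaly
  drug <- p$costs$monthly_drug_cost[["EPG_SOC"]]
  tab <- run_dsa(p, list(dsa_spec("costs.monthly_drug_cost.EPG_SOC",
                                  0.8 * drug, 1.2 * drug)))
  expect_lt(tab$icer_low, base)
  expect_gt(tab$icer_high, base)

  no_cv <- set_treatment_ratio(p, 1, "cv_death")
  icer_no_cv <- run_base_case(no_cv)$incremental$icer_per_qaly
  expect_gt(icer_no_cv, base)
})

test_that("failed overrides are flagged and the DSA continues", {
  p <- calibrated_bundle()
  specs <- list(
    dsa_spec("costs.hhf_cost", -10, -5, label = "broken"),   # invalid: < 0
    dsa_spec("costs.hhf_cost", 4000, 6000)
  )
  tab <- run_dsa(p, specs)
  expect_true(tab$failed[tab$parameter == "broken"])
  expect_false(tab$failed[tab$parameter == "costs.hhf_cost"])
  expect_true(all(is.finite(tab$icer_low[!tab$failed])))
})

test_that("tornado rows are sorted by bar width", {
  p <- calibrated_bundle()
  tab <- run_dsa(p, list(
    dsa_spec("costs.hhf_cost", p$costs$hhf_cost * 0.99, p$costs$hhf_cost * 1.01,
             label = "narrow"),
    dsa_spec("costs.monthly_drug_cost.EPG_SOC", 212 * 0.8, 212 * 1.2,
             label = "wide")))
  expect_identical(tab$parameter, c("wide", "narrow"))
  expect_true(all(diff(tab$width) <= 0))
})

test_that("PSA is reproducible under the seed and degenerate PSA is deterministic", {
  p <- calibrated_bundle()
  s1 <- run_psa(p, n = 4, seed = 17)
  s2 <- run_psa(p, n = 4, seed = 17)
  expect_identical(s1, s2)
  s3 <- run_psa(p, n = 4, seed = 18)
  expect_false(identical(s1$cost_epg_soc, s3$cost_epg_soc))

  # no distributions -> every iteration equals the deterministic run
  det <- run_base_case(p)
  s0 <- run_psa(p, dists = list(), n = 1, seed = 1)
  expect_equal(s0$cost_epg_soc, det$epg_soc$discounted$cost$total,
               tolerance = 1e-12)
  expect_equal(s0$qaly_soc, det$soc$discounted$qaly$total, tolerance = 1e-12)
  expect_equal(psa_mean_icer(s0)$mean_icer, det$incremental$icer_per_qaly,
               tolerance = 1e-12)
})

test_that("beta-distributed utility draws have the specified mean", {
  p <- calibrated_bundle()
  p$economics$horizon <- 24   # draws are what matters here, keep runs short
  dists <- list(psa_dist_spec("utilities.state_utility.Q1", "beta",
                              mean = 0.613))
  s <- run_psa(p, dists = dists, n = 400, seed = 7)
  draws <- vapply(attr(s, "draws"),
                  function(d) d[["utilities.state_utility.Q1"]], numeric(1))
  se <- 0.1 * 0.613 / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.613), 3 * se)
  expect_true(all(draws > 0 & draws < 1))
  expect_gt(stats::sd(draws), 0.02)
})

test_that("invalid draws are redrawn and exhaustion is a hard error", {
  p <- calibrated_bundle()
  p$economics$horizon <- 12
  # impossible bounds: every draw rejected, must fail loudly
  impossible <- psa_dist_spec("utilities.state_utility.Q1", "beta",
                              mean = 2.5)
  suppressWarnings(
    expect_error(run_psa(p, dists = list(impossible), n = 1, seed = 1),
                 "retries|invalid|beta")
  )
})

test_that("scenario runner reports percent change and leaves the base untouched", {
  p <- calibrated_bundle()
  snapshot <- serialize(p, NULL)
  base <- run_base_case(p)$incremental$icer_per_qaly

  tab0 <- run_scenarios(p, list())
  expect_equal(nrow(tab0), 1L)
  expect_identical(tab0$scenario, "base case")
  expect_equal(tab0$pct_change, 0)

  specs <- list(
    scenario_spec("discount 0%",
                  list(economics.annual_discount_rate_cost = 0,
                       economics.annual_discount_rate_benefit = 0)),
    scenario_spec("horizon 5 years", list(economics.horizon = 60)),
    scenario_spec("broken", list(costs.hhf_cost = -5))
  )
  tab <- run_scenarios(p, specs)
  # later benefits outweigh later costs here: discounting penalises the
  # intervention, so removing it lowers the ICER; truncating to 5 years
  # raises it
  expect_lt(tab$icer[tab$scenario == "discount 0%"], base)
  expect_gt(tab$icer[tab$scenario == "horizon 5 years"], base)
  expect_true(tab$failed[tab$scenario == "broken"])
  expect_identical(serialize(p, NULL), snapshot)
})

test_that("the default scenario catalogue runs and behaves qualitatively", {
  p <- calibrated_bundle()
  tab <- run_scenarios(p, scenario_default_specs(p))
  expect_false(any(tab$failed))
  base <- tab$icer[tab$scenario == "base case"]
  expect_gt(tab$icer[tab$scenario == "time horizon 5 years"], base)
  expect_gt(tab$icer[tab$scenario == "no CV death benefit"], base)
  expect_gt(tab$icer[tab$scenario == "T2D subgroup"],
            tab$icer[tab$scenario == "non-T2D subgroup"])
  # family swaps refit the base curve, so they move the ICER only modestly
  fam_rows <- grepl("extrapolation", tab$scenario)
  expect_true(all(abs(tab$icer[fam_rows] / base - 1) < 0.35))
})

test_that("refitted survival families track the base survivor curve", {
  p <- calibrated_bundle()
  base <- p$survival$cv_death
  for (fam in c("exponential", "lognormal", "loglogistic", "gompertz",
                "gengamma")) {
    alt <- refit_survival_family(base, fam)
    expect_identical(alt$family, fam)
    t <- c(6, 12, 24, 48)
    expect_equal(survival_probability(alt, t), survival_probability(base, t),
                 tolerance = 0.05, info = fam)
  }
  expect_identical(refit_survival_family(base, base$family), base)
})
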