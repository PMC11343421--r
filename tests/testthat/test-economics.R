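# Incremental results, net benefit, CEAC and phenotype pooling, checked by
# hand arithmetic and enumeration.

inc_of <- function(cost_a, qaly_a, cost_b, qaly_b, ly_a = qaly_a, ly_b = qaly_b) {
  incremental(list(cost = cost_a, ly = ly_a, qaly = qaly_a),
              list(cost = cost_b, ly = ly_b, qaly = qaly_b))
}

test_that("ICER arithmetic and dominance classification", {
  r <- inc_of(14000, 4.10, 10000, 4.00)
  expect_equal(r$delta_cost, 4000)
  expect_equal(r$delta_qaly, 0.10, tolerance = 1e-12)
  expect_equal(r$icer_per_qaly, 40000, tolerance = 1e-9)
  expect_identical(r$tag, "ratio")

  expect_identical(inc_of(9999, 4.01, 10000, 4.00)$tag, "dominant")
  expect_identical(inc_of(10001, 4.00, 10000, 4.00)$tag, "dominated")
  expect_identical(inc_of(10001, 3.99, 10000, 4.00)$tag, "dominated")

  same <- inc_of(10000, 4.00, 10000, 4.00)
  expect_equal(same$delta_cost, 0)
  expect_equal(same$delta_qaly, 0)
  expect_true(is.na(same$icer_per_qaly))
})

test_that("net monetary benefit matches hand arithmetic and the ICER rule", {
  expect_equal(net_monetary_benefit(3941, 0.10, 47439), 802.9,
               tolerance = 1e-9)
  expect_equal(net_monetary_benefit(0, 0, 47439), 0)
  # NMB > 0 <=> ICER < threshold whenever the QALY gain is positive
  set.seed(42)
  for (i in 1:200) {
    dc <- stats::runif(1, -5000, 20000)
    dq <- stats::runif(1, 1e-4, 0.5)
    l <- stats::runif(1, 0, 1e5)
    expect_identical(net_monetary_benefit(dc, dq, l) > 0, dc / dq < l)
  }
})

test_that("CEAC counts strictly positive NMB and partitions the two arms", {
  s <- make_psa_frame(dc = c(1000, -500, 2000, 0),
                      dq = c(0.05, 0.01, -0.01, 0))
  cc <- ceac(s, c(0, 50000))
  expect_equal(cc$prob_epg_soc, c(0.25, 0.50))
  expect_equal(cc$prob_epg_soc + cc$prob_soc, rep(1, 2))

  # boundary behaviour: lambda = 0 counts cost-saving iterations; a huge
  # lambda counts the QALY-gaining ones
  big <- ceac(s, c(0, 1e12))
  expect_equal(big$prob_epg_soc[1], mean(s$cost_epg_soc - s$cost_soc < 0))
  expect_equal(big$prob_epg_soc[2],
               mean(s$qaly_epg_soc - s$qaly_soc > 0))
  expect_error(ceac(s[0, ], 0), "empty")

  all_pos <- make_psa_frame(dc = c(-10, -20), dq = c(0.1, 0.2))
  expect_equal(ceac(all_pos, 47439)$prob_epg_soc, 1)
})

test_that("PSA mean ICER is the ratio of means", {
  s <- make_psa_frame(dc = c(100, 300), dq = c(0.01, 0.03))
  m <- psa_mean_icer(s)
  expect_equal(m$mean_icer, 200 / 0.02, tolerance = 1e-12)
  expect_equal(m$mean_delta_cost, 200)
  expect_equal(m$mean_delta_qaly, 0.02, tolerance = 1e-12)

  # homogeneity: scaling all costs scales the mean ICER
  s2 <- s
  s2$cost_epg_soc <- s2$cost_epg_soc * 3 - 2 * s2$cost_soc
  s2$cost_soc <- s2$cost_soc
  # equivalent to tripling the deltas
  expect_equal(psa_mean_icer(s2)$mean_icer, 3 * m$mean_icer, tolerance = 1e-9)

  # degenerate PSA (no variance) equals the deterministic ICER
  sd <- make_psa_frame(dc = rep(3941, 5), dq = rep(0.10, 5))
  expect_equal(psa_mean_icer(sd)$mean_icer, 3941 / 0.10, tolerance = 1e-9)
})

test_that("ICER is invariant to a constant cost added to both arms", {
  s <- make_psa_frame(dc = c(500, 1500, 2500), dq = c(0.02, 0.05, 0.08))
  shifted <- s
  shifted$cost_epg_soc <- shifted$cost_epg_soc + 12345
  shifted$cost_soc <- shifted$cost_soc + 12345
  expect_equal(psa_mean_icer(shifted)$mean_icer, psa_mean_icer(s)$mean_icer,
               tolerance = 1e-9)
})

test_that("deterministic phenotype pooling is the weighted mean of deltas", {
  r1 <- inc_of(13000, 4.2, 10000, 4.0)   # deltas 3000 / 0.2
  r2 <- inc_of(14000, 4.1, 10000, 4.0)   # deltas 4000 / 0.1
  pooled <- combine_phenotypes_deterministic(r1, r2, combine_spec(0.67, 0.33))
  expect_equal(pooled$delta_cost, 0.67 * 3000 + 0.33 * 4000, tolerance = 1e-12)
  expect_equal(pooled$delta_qaly, 0.67 * 0.2 + 0.33 * 0.1, tolerance = 1e-12)
  expect_equal(pooled$icer_per_qaly, 3330 / 0.167, tolerance = 1e-9)

  expect_equal(combine_phenotypes_deterministic(r1, r1)$icer_per_qaly,
               r1$icer_per_qaly, tolerance = 1e-12)
  # boundary weights return the corresponding input
  w10 <- combine_phenotypes_deterministic(
    r1, r2, combine_spec(1, 0, c(hfref = 1000L, ef40 = 0L)))
  expect_equal(w10$delta_cost, r1$delta_cost)
  expect_equal(w10$icer_per_qaly, r1$icer_per_qaly, tolerance = 1e-12)
})

test_that("PSA pooling resamples without replacement, reproducibly", {
  set.seed(99)
  s1 <- make_psa_frame(dc = rnorm(800, 3650, 400), dq = rnorm(800, 0.17, 0.05))
  s2 <- make_psa_frame(dc = rnorm(500, 3940, 400), dq = rnorm(500, 0.10, 0.05))
  sp <- combine_spec()

  p1 <- combine_phenotypes_psa(s1, s2, sp, seed = 5)
  p2 <- combine_phenotypes_psa(s1, s2, sp, seed = 5)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 1000L)
  expect_equal(sum(p1$phenotype == "hfref"), 670L)
  expect_equal(sum(p1$phenotype == "ef40"), 330L)
  expect_false(identical(p1$cost_epg_soc,
                         combine_phenotypes_psa(s1, s2, sp, seed = 6)$cost_epg_soc))

  # constant pools: pooled statistics equal that constant
  c1 <- make_psa_frame(dc = rep(3000, 700), dq = rep(0.2, 700))
  c2 <- make_psa_frame(dc = rep(3000, 400), dq = rep(0.2, 400))
  pc <- combine_phenotypes_psa(c1, c2, sp, seed = 1)
  expect_equal(unique(pc$cost_epg_soc - pc$cost_soc), 3000)

  # pool smaller than the resample count is an error
  expect_error(combine_phenotypes_psa(s1[1:100, ], s2, sp, seed = 1),
               "need 670")
})

test_that("pooled CEAC converges to the weighted phenotype probabilities", {
  set.seed(123)
  s1 <- make_psa_frame(dc = rnorm(5000, 3650, 900), dq = rnorm(5000, 0.17, 0.09))
  s2 <- make_psa_frame(dc = rnorm(5000, 3940, 900), dq = rnorm(5000, 0.10, 0.09))
  lambda <- 47439
  p_expected <- 0.67 * ceac(s1, lambda)$prob_epg_soc +
    0.33 * ceac(s2, lambda)$prob_epg_soc
  probs <- vapply(1:100, function(seed)
    ceac(combine_phenotypes_psa(s1, s2, combine_spec(), seed),
         lambda)$prob_epg_soc, numeric(1))
  expect_equal(mean(probs), p_expected, tolerance = 0.01)
})
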