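test_that("direct trait assortment alone reproduces the target couple correlation", {
  co <- default_cohort()  # n = 2e4, h2 = 0.2, r_x = 0.2
  n <- nrow(co$couples)
  expect_within(cor(co$index$X, co$partner$X), 0.2, 3 / sqrt(n))
  expect_equal(var(co$index$X), 1, tolerance = 0.05)
  expect_equal(var(co$partner$X), 1, tolerance = 0.05)
})

test_that("all four closed-form correlation expectations hold jointly", {
  # moderate parameter point: the closed forms are first-order path-tracing
  # approximations, exact as the parental terms shrink
  p <- couple_model_params(n_couples = 3e4, n_snps = 100, h2 = 0.2,
                           r_g = 0.05, r_e = 0.1, r_x = 0.1,
                           s_g = 0.05, s_x = 0.05, seed = 21)
  co <- simulate_couple_cohort(p)
  tol <- 3 / sqrt(p$n_couples)
  expected <- expected_couple_correlations(
    bias_params(h2 = 0.2, r_g = p$r_g, r_e = p$r_e, r_x = p$r_x,
                s_g = p$s_g, s_x = p$s_x))
  t_ge <- (p$s_g + p$g * p$s_x) / sqrt(2)
  expect_within(cor(co$index$X, co$partner$X), expected$corr_x, tol)
  expect_within(cor(co$index$E, co$partner$E), expected$corr_e, tol)
  expect_within(cor(co$index$G, co$partner$G), expected$corr_g, tol)
  expect_within(cor(co$index$G, co$index$E), t_ge, tol)
})

test_that("mean parental genetic score correlates 1/sqrt(2) with the offspring score", {
  co <- default_cohort()
  expect_within(cor(co$index$G_P, co$index$G), 1 / sqrt(2), 0.02)
  # and under nonzero assortment and parental effects as well
  p <- couple_model_params(n_couples = 2e4, h2 = 0.2, r_x = 0.2, r_e = 0.1,
                           s_x = 0.2, s_g = 0.1, seed = 22)
  co2 <- simulate_couple_cohort(p)
  expect_within(cor(co2$index$G_P, co2$index$G), 1 / sqrt(2), 0.02)
})

test_that("the independence case has no cross-partner structure", {
  p <- couple_model_params(n_couples = 2e4, h2 = 0.2, seed = 23)
  co <- simulate_couple_cohort(p)
  tol <- 3 / sqrt(p$n_couples)
  expect_lt(abs(cor(co$index$X, co$partner$X)), tol)
  expect_lt(abs(cor(co$index$G, co$partner$G)), tol)
  expect_lt(abs(cor(co$index$E, co$partner$E)), tol)
  expect_equal(var(co$index$X), 1, tolerance = 0.05)
})

test_that("infeasible correlation targets raise an infeasible-model error", {
  expect_error(couple_model_params(n_couples = 100, r_x = 0.6, r_e = 0.5),
               class = "couplemr_infeasible_model")
  expect_error(couple_model_params(n_couples = 100, r_x = 1.4),
               class = "couplemr_invalid_argument")
  expect_error(couple_model_params(n_couples = 100, g = 0.9, e = 0.9),
               class = "couplemr_invalid_argument")
  # parental effects that exceed the environmental variance
  p <- couple_model_params(n_couples = 1000, s_g = 0.8, s_e = 0.8, s_x = 0.8,
                           seed = 1)
  expect_error(simulate_couple_cohort(p), class = "couplemr_infeasible_model")
})

test_that("simulation is reproducible bit for bit under a fixed seed", {
  p <- couple_model_params(n_couples = 500, n_snps = 20, r_x = 0.2, seed = 99)
  expect_identical(simulate_couple_cohort(p), simulate_couple_cohort(p))
})

test_that("a pure-environment trait leaves MR without usable instruments", {
  p <- couple_model_params(n_couples = 5000, n_snps = 50, h2 = 0, r_x = 0.2,
                           seed = 24)
  co <- simulate_couple_cohort(p)
  expect_lt(summary(lm(co$index$X ~ co$index$G))$r.squared, 0.01)
  expect_error(single_trait_couple_mr(co, "X"),
               class = "couplemr_screen_failure")
})

test_that("couple convergence drift is recovered by the binned trend analysis", {
  p <- couple_model_params(n_couples = 2e4, h2 = 0.2, r_x = 0.15,
                           convergence_slope = 0.006, seed = 25)
  co <- simulate_couple_cohort(p)
  tr <- cohort_trend(co, "X", n_bins = 5)
  expect_within(tr$slope, 0.006, 2 * tr$se)
  expect_lt(tr$pval, 0.05)
})
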