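test_that("genotype-effect expectations evaluate the structural formulas", {
  p0 <- bias_params(h2 = 0.2)
  expect_equal(expected_beta_index(p0), sqrt(0.2))

  p1 <- bias_params(g = 0, e = 1, s_g = 0.1)
  expect_equal(expected_beta_index(p1), 0.1 / sqrt(2))

  # no assortment: genotype says nothing about the partner
  p2 <- bias_params(r_x = 0, s_g = 0.1, s_x = 0.2)
  expect_equal(expected_beta_partner(p2), 0)

  # single-path reduction: direct trait assortment only
  p3 <- bias_params(h2 = 0.2, r_x = 0.2)
  expect_equal(expected_beta_partner(p3), sqrt(0.2) * 0.2)
})

test_that("the MR expectation is unbiased absent violations and undefined at g = 0", {
  p <- bias_params(h2 = 0.2, r_x = 0.2)
  em <- expected_mr(p)
  expect_equal(em$expectation, 0.2)
  expect_equal(em$bias, 0)

  expect_error(expected_mr(bias_params(g = 0, e = 1, r_x = 0.2)),
               class = "couplemr_undefined_expectation")
})

test_that("bias is monotone in environmental assortment given parental effects", {
  biases <- sapply(seq(0, 0.3, by = 0.05), function(re)
    expected_mr(bias_params(h2 = 0.2, r_x = 0.2, r_e = re, s_x = 0.2))$bias)
  expect_true(all(diff(biases) > 0))
})

test_that("parental-environment transmission alone creates no bias", {
  for (se_ in c(-0.3, -0.1, 0.1, 0.3)) {
    p <- bias_params(h2 = 0.2, r_x = 0.2, s_e = se_)
    expect_equal(expected_mr(p)$bias, 0)
    expect_equal(expected_beta_index(p), sqrt(0.2))
    expect_equal(expected_beta_partner(p), sqrt(0.2) * 0.2)
  }
})

test_that("expected couple correlations reduce correctly", {
  p <- bias_params(h2 = 0.2, r_x = 0.2)
  cc <- expected_couple_correlations(p)
  expect_equal(cc$corr_x, 0.2)
  expect_equal(cc$corr_e, 0.2 * 0.8)
  expect_equal(cc$corr_g, 0.2 * 0.2)

  cc0 <- expected_couple_correlations(bias_params(r_x = 0))
  expect_equal(unlist(cc0), c(corr_x = 0, corr_e = 0, corr_g = 0))
})

test_that("derived violation magnitudes follow the genetic-correlation formulas", {
  expect_equal(unlist(derived_violation_params(sqrt(0.2), 0.3, 0, 0)),
               c(r_g = 0, s_g = 0))
  dv <- derived_violation_params(sqrt(0.2), 0.3, r_y = 0.3, s_y = 0.2)
  expect_equal(dv$r_g, 0.2 * 0.09 * 0.3)           # (g rG(X,Y))^2 rY = 0.0054
  expect_equal(dv$s_g, sqrt(0.2) * 0.3 * 0.2)
  # the explored grid ranges: |r_Y|, |s_Y| <= 0.3 map to small induced violations
  rg_max <- derived_violation_params(sqrt(0.2), 0.3, 0.3, 0.3)$r_g
  expect_lt(rg_max, 0.01)
})

test_that("the bias grid is consistent with pointwise evaluation", {
  base <- bias_params(h2 = 0.2, r_x = 0.2)
  grid <- bias_grid(base, c("r_e", "s_x"),
                    list(c(-0.3, 0.3), c(-0.3, 0.3)), resolution = 5)
  expect_equal(nrow(grid), 25)
  i <- 17
  pt <- bias_params(h2 = 0.2, r_x = 0.2, r_e = grid$r_e[i], s_x = grid$s_x[i])
  expect_equal(grid$bias[i], expected_mr(pt)$bias)
  # the no-violation row is exactly unbiased
  expect_true(all(grid$bias[grid$s_x == 0] == 0))

  # genotype assortment at its derived magnitude is dwarfed by environmental
  # assortment at matched coordinates
  g_ax <- bias_grid(base, c("r_g", "r_e"), list(c(0, 0.0054), c(0, 0.3)),
                    resolution = 3)
  bias_rg <- g_ax$bias[g_ax$r_g == 0.0054 & g_ax$r_e == 0]
  bias_re <- expected_mr(bias_params(h2 = 0.2, r_x = 0.2, r_e = 0.3,
                                     s_x = 0.2))$bias
  expect_lt(abs(bias_rg), abs(bias_re))
  expect_error(bias_grid(base, c("r_e", "nope"), list(c(0, 1), c(0, 1))),
               class = "couplemr_invalid_argument")
})
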