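test_that("gamma is the product of the two path estimates with propagated se", {
  expect_equal(estimate_gamma(0, 0.01, 0.5, 0.01)$gamma, 0)
  expect_equal(estimate_gamma(0.2, 0.01, 0.3, 0.01)$gamma, 0.06)

  # se propagation against a Monte-Carlo product oracle
  set.seed(71)
  cases <- list(c(0.2, 0.02, 0.3, 0.03), c(-0.4, 0.05, 0.25, 0.01))
  for (cs in cases) {
    mc <- sd(rnorm(1e6, cs[1], cs[2]) * rnorm(1e6, cs[3], cs[4]))
    expect_within(estimate_gamma(cs[1], cs[2], cs[3], cs[4])$se, mc, 0.02 * mc)
  }
})

test_that("rho takes the MVMR Y_i coefficient times the within-person effect", {
  mv <- data.frame(exposure = c("Y_i", "X_i"), beta = c(0.25, 0.01),
                   se = c(0.02, 0.02), pval = c(0, 0.5))
  rho <- estimate_rho(mv, 0.3, 0.01)
  expect_equal(rho$rho, 0.075)
  expect_equal(rho$alpha_yi_yp, 0.25)
  expect_equal(rho$se, product_se(0.25, 0.02, 0.3, 0.01))
  expect_error(estimate_rho(mv[2, ], 0.3, 0.01),
               class = "couplemr_invalid_argument")
})

test_that("residualizing rho on gamma matches ordinary least squares", {
  g <- c(1, 2, 3, 4, 5)
  expect_equal(residualize_rho(2 * g + 1, g), rep(0, 5))

  set.seed(72)
  rho <- rnorm(5); gam <- rnorm(5)
  res <- residualize_rho(rho, gam)
  X <- cbind(1, gam)
  ref <- rho - X %*% solve(crossprod(X), crossprod(X, rho))
  expect_equal(res, drop(ref), tolerance = 1e-10, ignore_attr = TRUE)
  expect_lt(abs(cor(res, gam)), 1e-10)

  # orthogonal case: residual is the centred rho
  rho_o <- c(1, -1, 2, -2, 0)
  gam_o <- c(1, 1, 1, 1, 1) + c(0.1, -0.1, 0, 0, 0)
  r2 <- residualize_rho(rho_o, gam_o)
  expect_equal(length(r2), 5)
  expect_error(residualize_rho(rho, rep(1, 5)),
               class = "couplemr_invalid_argument")
})

test_that("compare_paths reports contrasts, paired test and origin regression", {
  set.seed(73)
  n <- 12
  gam <- runif(n, 0.02, 0.1)
  rho <- gam  # identical paths
  paths <- data.frame(pair = paste0("p", 1:n), omega = gam + rho / 2,
                      se_omega = 0.01, gamma = gam, se_gamma = 0.01,
                      rho = rho, se_rho = 0.01)
  out <- suppressWarnings(compare_paths(paths))
  expect_equal(unname(out$paired_t$statistic), 0)
  expect_true(all(out$paths$p_rho_gamma == 1))

  # omega exactly gamma + rho_resid: slope 1, R2 1
  paths2 <- paths
  paths2$rho <- rnorm(n, 0.05, 0.03)
  rr <- residualize_rho(paths2$rho, paths2$gamma)
  paths2$omega <- paths2$gamma + rr
  out2 <- suppressWarnings(compare_paths(paths2))
  expect_equal(out2$origin_slope, 1, tolerance = 1e-10)
  expect_equal(out2$r2_origin, 1, tolerance = 1e-10)

  # sign-mismatch exclusion before the paired t test
  paths3 <- paths
  paths3$rho[1:3] <- -paths3$rho[1:3]
  out3 <- compare_paths(paths3)
  expect_equal(out3$n_sign_mismatch, 3)
})

test_that("redundant trait pairs are pruned prioritizing smaller omega p-values", {
  traits <- c("A", "B", "C", "D")
  R <- diag(4); dimnames(R) <- list(traits, traits)
  R["A", "C"] <- R["C", "A"] <- 0.95
  R["B", "D"] <- R["D", "B"] <- 0.95
  pairs <- data.frame(pair = c("AB", "CD"),
                      trait_x = c("A", "C"), trait_y = c("B", "D"),
                      p_omega = c(1e-8, 1e-4))
  # corr(A,C)*corr(B,D) = 0.9 > 0.8: drop the larger-p pair (CD)
  kept <- prune_trait_pairs(pairs, R)
  expect_identical(kept$pair, "AB")

  R["A", "C"] <- R["C", "A"] <- 0.5
  expect_equal(nrow(prune_trait_pairs(pairs, R)), 2)
})

test_that("path decomposition recovers the generative design", {
  # exposure assortment only: omega ~ gamma, rho ~ 0
  np <- trait_network_params(n_couples = 3e4, alpha_x_to_y = 0.3, r_x = 0.2,
                             seed = 74)
  pa <- path_analysis(simulate_trait_network(np))
  expect_within(pa$omega, 0.06, 2 * pa$se_omega)
  expect_within(pa$gamma, 0.06, 2.5 * pa$se_gamma)
  expect_within(pa$rho, 0, 2.5 * pa$se_rho)

  # outcome assortment only: omega ~ rho, gamma ~ 0
  np2 <- trait_network_params(n_couples = 3e4, alpha_x_to_y = 0.3, r_y = 0.2,
                              seed = 75)
  pa2 <- path_analysis(simulate_trait_network(np2))
  expect_within(pa2$omega, 0.06, 2 * pa2$se_omega)
  expect_within(pa2$rho, 0.06, 2.5 * pa2$se_rho)
  # assortment on Y leaks a small X similarity through the X -> Y path:
  # alpha_xi_xp = r_y * alpha^2, hence gamma = r_y * alpha^3 << rho
  expect_within(pa2$gamma, 0.2 * 0.3^3, 2.5 * pa2$se_gamma)
  expect_lt(abs(pa2$gamma), abs(pa2$rho) / 2)
  expect_within(pa2$alpha_yi_yp_mvmr, 0.2, 2.5 * pa2$se_yi_yp_mvmr)

  # near-duplicate pair screen
  expect_error(estimate_omega(random_stats(5, 1), random_stats(5, 2),
                              pair_corr = 0.85),
               class = "couplemr_screen_failure")
})
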