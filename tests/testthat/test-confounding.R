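test_that("confounding correlation follows C = a^2 * couple effect", {
  expect_equal(confounding_correlation(0, 0.7), 0)
  expect_equal(confounding_correlation(0.5, 0.4), 0.1)
  expect_equal(confounding_correlation(0.5, -0.4), -0.1)
  expect_equal(confounding_correlation(-0.5, 0.4), 0.1)
})

test_that("Var(C) matches a large Monte-Carlo oracle within 2%", {
  expect_equal(confounding_variance(0.5, 0, 0.4, 0), 0)
  # central chi-square limb: Var(A) = 2 sigma^4 when mu = 0
  expect_equal(confounding_variance(0, 1, 1, 0), 2)

  cases <- list(c(0.5, 0.1, 0.4, 0.05),
                c(0.3, 0.05, -0.2, 0.1),
                c(0.8, 0.02, 0.6, 0.02))
  set.seed(61)
  for (cs in cases) {
    a <- rnorm(1e6, cs[1], cs[2])^2
    b <- rnorm(1e6, cs[3], cs[4])
    mc <- var(a * b)
    expect_within(confounding_variance(cs[1], cs[2], cs[3], cs[4]), mc, 0.02 * mc)
  }
})

test_that("the confounder scan applies its three sequential filters", {
  meff <- 10
  cand <- data.frame(
    trait = c("null_y", "near_dup", "real", "weak_couple"),
    alpha_y_to_x = c(0.01, 0.5, 0.5, 0.4),
    se_y_to_x = c(0.01, 0.01, 0.01, 0.01),
    p_y_to_x = c(0.4, 1e-20, 1e-20, 1e-12),
    alpha_yi_to_yp = c(0.3, 0.4, 0.4, 0.01),
    se_yi_to_yp = c(0.01, 0.01, 0.01, 0.01),
    p_yi_to_yp = c(1e-10, 1e-10, 1e-10, 0.5),
    corr_with_x = c(0.2, 0.9, 0.3, 0.1))
  out <- confounder_scan(cand, meff)
  expect_identical(out$retained, c(FALSE, FALSE, TRUE, FALSE))
  expect_false(out$pass_effect[1])
  expect_false(out$pass_corr[2])
  expect_false(out$pass_couple[4])
  expect_equal(out$C[3], 0.1)
})

test_that("confounder pruning is greedy by |C| and sums retained variances", {
  cf <- data.frame(trait = c("a", "b", "c", "d"),
                   C = c(0.10, 0.09, 0.05, 0.02),
                   var_C = c(1e-4, 1e-4, 4e-4, 1e-4))
  rmat <- diag(4); dimnames(rmat) <- list(cf$trait, cf$trait)
  # uncorrelated: all retained
  all_in <- prune_confounders(cf, rmat)
  expect_setequal(all_in$retained, cf$trait)
  expect_equal(all_in$C_sum, sum(cf$C))
  expect_equal(all_in$var_C_sum, sum(cf$var_C))

  # a and b near-duplicates: larger-|C| member (a) wins
  rmat["a", "b"] <- rmat["b", "a"] <- 0.9
  pr <- prune_confounders(cf, rmat)
  expect_true("a" %in% pr$retained)
  expect_false("b" %in% pr$retained)

  # independent brute-force greedy reference on a random instance
  set.seed(62)
  R <- matrix(runif(16, -0.8, 0.8), 4); R <- (R + t(R)) / 2; diag(R) <- 1
  dimnames(R) <- list(cf$trait, cf$trait)
  ref <- character(0)
  for (id in cf$trait[order(-abs(cf$C), cf$trait)])
    if (all(R[id, ref]^2 < 0.1)) ref <- c(ref, id)
  expect_setequal(prune_confounders(cf, R)$retained, ref)

  # order invariance of the input rows
  shuffled <- cf[c(3, 1, 4, 2), ]
  expect_equal(prune_confounders(shuffled, R)$C_sum,
               prune_confounders(cf, R)$C_sum)
})

test_that("confounding ratio handles full, null and undefined cases", {
  expect_equal(confounding_ratio(0.15, 0.15), 1)
  expect_equal(confounding_ratio(0, 0.3), 0)
  expect_error(confounding_ratio(0.1, 0), class = "couplemr_undefined_ratio")
})

test_that("a confounder-only cohort yields ratio near 1 and C near r - alpha", {
  np <- trait_network_params(n_couples = 3e4, alpha_y_to_x = 0.5, r_y = 0.4,
                             r_x = 0, seed = 63)
  res <- confounding_analysis(simulate_trait_network(np))
  expect_within(res$alpha_y_to_x, 0.5, 2.5 * res$se_y_to_x)
  expect_within(res$alpha_yi_to_yp, 0.4, 2.5 * res$se_yi_to_yp)
  gap <- res$couple_r - res$IVW_beta_x
  se_gap <- sqrt(res$couple_r_se^2 + res$IVW_se_x^2 + res$se_C^2)
  expect_within(res$C, gap, 2 * se_gap)
  expect_within(res$confounding_ratio, 1, 0.25)
})
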