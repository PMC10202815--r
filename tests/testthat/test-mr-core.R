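test_that("IVW reduces to the Wald ratio and matches the closed form", {
  w <- ivw_estimate(2, 1, 1)
  expect_equal(w$alpha, 0.5)
  expect_equal(w$se^2, 0.25)
  expect_equal(w$k, 1)
  expect_true(is.na(w$q_pval))

  est <- ivw_estimate(c(1, 2, 3), c(0.5, 1.2, 1.4), c(1, 1, 1))
  expect_equal(est$alpha, 7.1 / 14)
  expect_equal(est$se, 1 / sqrt(14))

  expect_equal(ivw_estimate(c(1, 2), c(0, 0), c(1, 1))$alpha, 0)
  expect_error(ivw_estimate(c(0, 0), c(1, 1), c(1, 1)),
               class = "couplemr_invalid_argument")
})

test_that("IVW equals the weighted through-origin least-squares slope", {
  for (i in 1:200) {
    set.seed(i)
    k <- sample(2:30, 1)
    bx <- rnorm(k); by <- rnorm(k); se <- runif(k, 0.1, 2)
    est <- ivw_estimate(bx, by, se)
    fit <- lm(by ~ 0 + bx, weights = se^-2)
    expect_equal(est$alpha, unname(coef(fit)), tolerance = 1e-10)
  }
})

test_that("IVW scaling behaviour follows the estimator algebra", {
  set.seed(7)
  bx <- rnorm(10); by <- rnorm(10); se <- runif(10, 0.5, 1)
  base <- ivw_estimate(bx, by, se)
  scaled_y <- ivw_estimate(bx, 3 * by, 3 * se)
  expect_equal(scaled_y$alpha, 3 * base$alpha)
  expect_equal(scaled_y$se, 3 * base$se)
  scaled_x <- ivw_estimate(2 * bx, by, se)
  expect_equal(scaled_x$alpha, base$alpha / 2)
})

test_that("Cochran's Q detects heterogeneity and degenerates gracefully", {
  # identical Wald ratios: no heterogeneity
  q0 <- cochran_q(c(1, 2, 4), c(0.5, 1, 2), c(1, 1, 1), 0.5)
  expect_equal(q0$q, 0)
  expect_equal(q0$pval, 1)
  # direct evaluation oracle
  q <- cochran_q(c(1, 1), c(0, 1), c(1, 1), 0.5)
  expect_equal(q$q, 0.5)
  expect_equal(q$df, 1)
  # single instrument: no p-value fabricated
  q1 <- cochran_q(1, 0.5, 1, 0.5)
  expect_equal(q1$df, 0)
  expect_true(is.na(q1$pval))
})

test_that("effect standardization is the exact z-to-r conversion", {
  s0 <- standardize_effects(0, 0.1, 100)
  expect_equal(s0$beta, 0)
  expect_equal(s0$se, 1 / sqrt(98))

  s <- standardize_effects(0.5, 0.1, 1e4)  # z = 5
  expect_equal(s$beta, 5 / sqrt(9998 + 25), tolerance = 1e-12)
  expect_equal(s$beta, 0.04994, tolerance = 1e-4)

  set.seed(8)
  b <- rnorm(50); se <- runif(50, 0.01, 1)
  s2 <- standardize_effects(b, se, 1000)
  expect_identical(sign(s2$beta), sign(b))
  expect_error(standardize_effects(1, 0.1, 2), class = "couplemr_invalid_argument")
})

test_that("the Steiger filter removes only significant reverse-signal SNPs", {
  # correct orientation everywhere: all retained
  expect_true(all(steiger_filter(c(0.3, 0.2), c(0.01, 0.01),
                                 c(0.1, 0.05), c(0.01, 0.01))))
  # overwhelming reverse signal: removed
  expect_false(suppressWarnings(steiger_filter(0.01, 0.001, 0.3, 0.001)))
  # reverse but not significant at 0.001: retained
  expect_true(steiger_filter(0.05, 0.01, 0.06, 0.01))
  # threshold limits
  b <- rnorm(20, 0, 0.1); se <- rep(0.01, 20)
  o <- rnorm(20, 0, 0.1)
  expect_true(all(steiger_filter(b, se, o, se, p_threshold = 1e-300)))
  suppressWarnings(
    expect_identical(steiger_filter(b, se, o, se, p_threshold = 1),
                     !(abs(o) > abs(b))))
})

test_that("fixed-effect meta-analysis pools by inverse variance", {
  m <- meta_fixed(0.3, 0.1, 0.3, 0.1)
  expect_equal(m$beta, 0.3)
  expect_equal(m$se, 0.1 / sqrt(2))

  m2 <- meta_fixed(0.2, 0.1, 0.4, 0.2)
  expect_equal(m2$beta, 0.24)
  expect_equal(m2$se, 1 / sqrt(125))

  m3 <- meta_fixed(0.2, 0.1, 5, Inf)
  expect_equal(m3$beta, 0.2)
  expect_equal(m3$se, 0.1)
})

test_that("MVMR matches the weighted normal equations and flags collinearity", {
  set.seed(9)
  k <- 12
  X <- cbind(a = rnorm(k), b = rnorm(k))
  beta_out <- X %*% c(0.5, -0.2) + rnorm(k, 0, 0.05)
  se <- runif(k, 0.05, 0.2)
  est <- mvmr_estimate(drop(beta_out), se, X)
  fit <- lm(drop(beta_out) ~ 0 + X, weights = se^-2)
  expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)

  # nested model: an all-zero second exposure column drops out and the first
  # coefficient equals the univariable IVW
  X2 <- cbind(a = X[, 1], b = 0)
  est2 <- mvmr_estimate(drop(beta_out), se, X2)
  uni <- ivw_estimate(X[, 1], drop(beta_out), se)
  expect_equal(est2$beta[1], uni$alpha, tolerance = 1e-12)
  expect_true(is.na(est2$beta[2]))

  expect_error(mvmr_estimate(drop(beta_out), se, cbind(X[, 1], 2 * X[, 1])),
               class = "couplemr_collinearity")
  expect_error(mvmr_estimate(beta_out[1:2], se[1:2], X[1:2, ]),
               class = "couplemr_invalid_argument")
})

test_that("instrument selection prunes by LD with greedy p-value order", {
  st <- random_stats(5, seed = 10)
  st$pval <- c(1e-10, 1e-9, 1e-12, 0.5, 1e-8)
  # identity LD: every significant SNP retained, ordered by p
  eye <- diag(5); dimnames(eye) <- list(st$snp, st$snp)
  sel <- select_instruments(st, ld = eye, p_threshold = 5e-8)
  expect_identical(sel$snp, c("snp3", "snp1", "snp2", "snp5"))

  # perfectly correlated duplicate: smaller-p member wins
  ld <- diag(5); dimnames(ld) <- list(st$snp, st$snp)
  ld["snp1", "snp2"] <- ld["snp2", "snp1"] <- 1
  sel2 <- select_instruments(st, ld = ld, p_threshold = 5e-8)
  expect_true("snp1" %in% sel2$snp)
  expect_false("snp2" %in% sel2$snp)

  # toy LD structure: matches an independent brute-force greedy reference
  set.seed(11)
  L <- matrix(runif(25, -0.9, 0.9), 5); L <- (L + t(L)) / 2; diag(L) <- 1
  dimnames(L) <- list(st$snp, st$snp)
  sel3 <- select_instruments(st, ld = L, p_threshold = 5e-8, r2_threshold = 0.1)
  ref <- character(0)
  for (id in st$snp[order(st$pval)][st$pval[order(st$pval)] < 5e-8]) {
    if (all(L[id, ref]^2 < 0.1)) ref <- c(ref, id)
  }
  expect_setequal(sel3$snp, ref)
})

test_that("sex-heterogeneity filtering applies the Bonferroni-corrected Z test", {
  expect_true(all(sex_heterogeneity_filter(c(0.1, 0.2), c(0.01, 0.01),
                                           c(0.1, 0.2), c(0.01, 0.01), 10)))
  expect_false(sex_heterogeneity_filter(0.5, 0.01, -0.5, 0.01, 10))
  # |Z| = 3.0 vs threshold qnorm(1 - 0.0025) = 2.807: removed
  expect_false(sex_heterogeneity_filter(0.3, 0.1 / sqrt(2), 0, 0.1 / sqrt(2), 10))
  # same Z against a single-test threshold 1.96 < 3: still removed; Z = 1.5 kept
  expect_false(sex_heterogeneity_filter(0.3, 0.1 / sqrt(2), 0, 0.1 / sqrt(2), 1))
  expect_true(sex_heterogeneity_filter(0.15, 0.1 / sqrt(2), 0, 0.1 / sqrt(2), 10))
})
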