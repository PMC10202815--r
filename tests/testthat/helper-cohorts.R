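# shared, lazily built mid-size cohorts so several test files can reuse one
# simulation; all test randomness is seeded explicitly

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

default_cohort <- function() fixture("default", function()
  simulate_couple_cohort(couple_model_params(
    n_couples = 20000, n_snps = 100, h2 = 0.2, r_x = 0.2, seed = 1)))

# absolute-tolerance comparison for Monte-Carlo bounds (expect_equal treats
# `tolerance` as relative for values away from zero)
expect_within <- function(object, expected, tol, label = NULL) {
  act <- testthat::quasi_label(rlang::enquo(object), label)
  testthat::expect(abs(act$val - expected) < tol,
                   sprintf("%s (= %.5f) differs from %.5f by %.5f, beyond %.5f",
                           act$lab, act$val, expected,
                           abs(act$val - expected), tol))
  invisible(act$val)
}

# random summary-statistics table for estimator round-trips
random_stats <- function(k, seed) {
  set.seed(seed)
  data.frame(snp = paste0("snp", 1:k),
             effect_allele = sample(c("A", "C"), k, TRUE),
             other_allele = "G",
             beta = rnorm(k, 0, 0.05),
             se = runif(k, 0.005, 0.02),
             n = sample(1000:50000, k, TRUE),
             pval = runif(k),
             stringsAsFactors = FALSE)
}
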