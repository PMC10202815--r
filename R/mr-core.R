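#' Inverse-variance weighted MR estimate
#'
#' Combines per-variant Wald ratios with inverse-variance weights:
#' \deqn{\hat\alpha = \frac{\sum_k \beta_k^X \beta_k^Y (\sigma_k^Y)^{-2}}
#'                         {\sum_k (\beta_k^X)^2 (\sigma_k^Y)^{-2}},\quad
#'       Var(\hat\alpha) = \frac{1}{\sum_k (\beta_k^X)^2 (\sigma_k^Y)^{-2}}}
#' which is exactly the no-intercept weighted least-squares slope of outcome
#' effects on exposure effects with weights \eqn{(\sigma_k^Y)^{-2}}. With a
#' single instrument this reduces to the Wald ratio \eqn{\beta^Y/\beta^X}.
#'
#' @param beta_x per-variant effects on the exposure.
#' @param beta_y per-variant effects on the outcome.
#' @param se_y standard errors of `beta_y`.
#' @return an object of class `mr_estimate`: list with `alpha`, `se`, `pval`
#'   (two-sided normal), `k`, and Cochran's heterogeneity `q`, `q_df`, `q_pval`.
#' @export
ivw_estimate <- function(beta_x, beta_y, se_y) {
  k <- length(beta_x)
  if (k < 1 || length(beta_y) != k || length(se_y) != k)
    stop_invalid("beta_x, beta_y, se_y must have equal positive length")
  if (any(se_y <= 0)) stop_invalid("se_y must be positive")
  if (all(beta_x == 0))
    stop_invalid("all exposure effects are zero: no instrument strength")
  w <- se_y^-2
  denom <- sum(beta_x^2 * w)
  alpha <- sum(beta_x * beta_y * w) / denom
  se <- sqrt(1 / denom)
  q <- cochran_q(beta_x, beta_y, se_y, alpha)
  structure(list(alpha = alpha, se = se,
                 pval = 2 * stats::pnorm(-abs(alpha / se)),
                 k = k, q = q$q, q_df = q$df, q_pval = q$pval),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("IVW MR estimate: alpha = %.4f (se %.4f), p = %.3g, k = %d, Q = %.2f (df %d)\n",
              x$alpha, x$se, x$pval, x$k, x$q, x$q_df))
  invisible(x)
}

#' Cochran's heterogeneity Q across instruments
#'
#' \eqn{Q = \sum_k w_k (\beta_k^Y/\beta_k^X - \alpha)^2} with weights
#' \eqn{w_k = (\beta_k^X)^2/(\sigma_k^Y)^2} (the delta-method precision of the
#' Wald ratio, consistent with the IVW weights); p-value from a chi-square
#' distribution with k - 1 degrees of freedom.
#'
#' @inheritParams ivw_estimate
#' @param alpha the pooled (IVW) estimate.
#' @return list with `q`, `df`, `pval` (`pval` is `NA` when `k = 1`).
#' @export
cochran_q <- function(beta_x, beta_y, se_y, alpha) {
  k <- length(beta_x)
  w <- beta_x^2 / se_y^2
  q <- sum(w * (beta_y / beta_x - alpha)^2)
  df <- k - 1L
  list(q = q, df = df,
       pval = if (df >= 1) stats::pchisq(q, df, lower.tail = FALSE) else NA_real_)
}

#' Standardize summary-statistic effects to the correlation scale
#'
#' Converts per-variant effects so that the squared standardized effect is the
#' variance explained: \eqn{b_{std} = z/\sqrt{n - 2 + z^2}} with
#' \eqn{z = \beta/se}, and \eqn{se_{std} = 1/\sqrt{n - 2 + z^2}} (exact for a
#' univariate regression on standardized variables; needs only beta, se, n).
#'
#' @param beta,se effect and standard error.
#' @param n sample size (>= 3).
#' @return list with `beta` and `se` on the standardized scale.
#' @export
standardize_effects <- function(beta, se, n) {
  if (any(n < 3)) stop_invalid("n must be >= 3")
  if (any(se <= 0)) stop_invalid("se must be positive")
  z <- beta / se
  denom <- sqrt(n - 2 + z^2)
  list(beta = z / denom, se = 1 / denom)
}

#' Steiger directionality filter
#'
#' Removes instruments with evidence of acting on the outcome more strongly
#' than on the exposure (reverse causation): a SNP is dropped iff its absolute
#' standardized outcome effect exceeds the absolute standardized exposure
#' effect and the one-tailed test of the difference (normal approximation,
#' independent-sample variance \eqn{se_x^2 + se_y^2}) is significant at
#' `p_threshold`.
#'
#' @param exp_beta,exp_se standardized exposure effects and their ses.
#' @param out_beta,out_se standardized outcome effects and their ses.
#' @param p_threshold one-tailed significance threshold (default 0.001).
#' @return logical vector: `TRUE` for retained instruments.
#' @export
steiger_filter <- function(exp_beta, exp_se, out_beta, out_se, p_threshold = 0.001) {
  k <- length(exp_beta)
  stopifnot(length(out_beta) == k, length(exp_se) == k, length(out_se) == k)
  z <- (abs(out_beta) - abs(exp_beta)) / sqrt(exp_se^2 + out_se^2)
  p_one <- stats::pnorm(z, lower.tail = FALSE)
  retained <- !(abs(out_beta) > abs(exp_beta) & p_one < p_threshold)
  if (!any(retained)) warning("Steiger filter removed every instrument")
  retained
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' @param beta_a,se_a,beta_b,se_b estimates and standard errors from the two
#'   strata (vectorized, e.g. per SNP).
#' @return list with pooled `beta` and `se`. Infinite ses receive zero weight.
#' @export
meta_fixed <- function(beta_a, se_a, beta_b, se_b) {
  if (any(c(se_a, se_b) <= 0)) stop_invalid("standard errors must be positive")
  wa <- se_a^-2; wb <- se_b^-2
  list(beta = (beta_a * wa + beta_b * wb) / (wa + wb),
       se = 1 / sqrt(wa + wb))
}

#' Multivariable MR by weighted regression of outcome on exposure effects
#'
#' Regresses per-variant outcome effects jointly on several exposures'
#' per-variant effects, without intercept, weighted by `se_out^-2`; the
#' coefficient of each exposure is its direct causal effect conditional on the
#' others.
#'
#' @param beta_out per-variant outcome effects.
#' @param se_out their standard errors.
#' @param beta_exposures matrix (variants x exposures) of exposure effects.
#' @return data.frame with one row per exposure: `exposure`, `beta`, `se`,
#'   `pval`.
#' @export
mvmr_estimate <- function(beta_out, se_out, beta_exposures) {
  X <- as.matrix(beta_exposures)
  k <- length(beta_out); p <- ncol(X)
  if (nrow(X) != k || length(se_out) != k) stop_invalid("dimension mismatch")
  if (k < p + 1) stop_invalid("need at least one more instrument than exposures")
  labels <- colnames(X) %||% paste0("exposure", seq_len(p))
  # exposures with no instrument strength at all drop out of the fit (their
  # direct effect is not identified); the remaining model is the nested MVMR
  keep <- colSums(X != 0) > 0
  Xk <- X[, keep, drop = FALSE]
  if (ncol(Xk) < 1) stop_invalid("all exposure effects are zero")
  if (qr(Xk)$rank < ncol(Xk))
    stop(structure(class = c("couplemr_collinearity", "error", "condition"),
                   list(message = "exposure effect matrix is rank deficient (collinear exposures)",
                        call = sys.call())))
  w <- se_out^-2
  xtwx <- crossprod(Xk * sqrt(w))
  coef <- se <- rep(NA_real_, p)
  coef[keep] <- solve(xtwx, crossprod(Xk, w * beta_out))
  se[keep] <- sqrt(diag(solve(xtwx)))
  z <- coef / se
  data.frame(exposure = labels, beta = coef, se = se,
             pval = 2 * stats::pnorm(-abs(z)),
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select independent genome-wide-significant instruments
#'
#' Greedy selection mirroring LD clumping: order variants by ascending
#' association p-value, keep those with `pval < p_threshold`, and accept a
#' variant only if its squared correlation with every previously accepted
#' variant is below `r2_threshold`.
#'
#' @param stats summary-statistics data.frame (`snp`, `beta`, `se`, `n`, `pval`).
#' @param ld optional LD correlation matrix with SNP ids as dimnames; `NULL`
#'   treats all variants as independent.
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param r2_threshold LD pruning threshold (default 0.001).
#' @return the retained rows of `stats` (possibly zero rows; downstream screens
#'   enforce the minimum instrument count).
#' @export
select_instruments <- function(stats, ld = NULL, p_threshold = 5e-8,
                               r2_threshold = 0.001) {
  sig <- stats[stats$pval < p_threshold, , drop = FALSE]
  sig <- sig[order(sig$pval), , drop = FALSE]
  if (is.null(ld) || nrow(sig) <= 1) return(sig)
  if (!isTRUE(all.equal(ld, t(ld), tolerance = 1e-8)) ||
      !isTRUE(all.equal(unname(diag(ld)), rep(1, nrow(ld)))))
    stop_invalid("ld must be symmetric with unit diagonal")
  accepted <- integer(0)
  for (i in seq_len(nrow(sig))) {
    id <- sig$snp[i]
    if (length(accepted) == 0 ||
        all(ld[id, sig$snp[accepted]]^2 < r2_threshold))
      accepted <- c(accepted, i)
  }
  sig[accepted, , drop = FALSE]
}

#' Filter instruments with significant between-sex effect heterogeneity
#'
#' Per-SNP two-sample Z test of the male versus female effect; a SNP is removed
#' iff its heterogeneity p-value is below the Bonferroni threshold
#' `0.05 / n_ivs`.
#'
#' @param beta_m,se_m,beta_f,se_f sex-specific effects and standard errors.
#' @param n_ivs number of instruments tested (Bonferroni denominator).
#' @return logical vector: `TRUE` for retained instruments.
#' @export
sex_heterogeneity_filter <- function(beta_m, se_m, beta_f, se_f, n_ivs = length(beta_m)) {
  z <- (beta_m - beta_f) / sqrt(se_m^2 + se_f^2)
  p <- 2 * stats::pnorm(-abs(z))
  p >= 0.05 / n_ivs
}
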