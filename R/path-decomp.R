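#' Total cross-trait cross-partner effect (omega)
#'
#' IVW MR with trait X of the index person as exposure and trait Y of the
#' partner as outcome, after Steiger filtering of the instruments for reverse
#' causation. Trait pairs with absolute phenotypic correlation at or above
#' `corr_cap` are refused (near-duplicate traits).
#'
#' @param exp_stats exposure (X) summary statistics.
#' @param out_stats outcome (Y in the partner, on index genotypes) summary
#'   statistics.
#' @param pair_corr phenotypic correlation between X and Y (same person).
#' @param corr_cap near-duplicate cap (default 0.8).
#' @param steiger_p Steiger threshold (default 0.001).
#' @param min_ivs minimum surviving instruments (default 5).
#' @return an `mr_estimate` for omega.
#' @export
estimate_omega <- function(exp_stats, out_stats, pair_corr = 0,
                           corr_cap = 0.8, steiger_p = 0.001, min_ivs = 5) {
  if (abs(pair_corr) >= corr_cap)
    stop(structure(class = c("couplemr_screen_failure", "error", "condition"),
                   list(message = sprintf(
                     "trait pair skipped: |phenotypic correlation| = %.2f >= %.2f",
                     abs(pair_corr), corr_cap), call = sys.call())))
  couple_mr_from_stats(exp_stats, out_stats, steiger_p = steiger_p,
                       min_ivs = min_ivs)
}

# standard error of a product of two independent estimates
product_se <- function(a, se_a, b, se_b) {
  sqrt(se_a^2 * se_b^2 + se_a^2 * b^2 + se_b^2 * a^2)
}

#' Exposure-assortment path (gamma)
#'
#' \eqn{\gamma = \alpha_{x_i \to x_p} \cdot \alpha_{x \to y}}: the single-trait
#' couple effect on X times the within-person causal effect of X on Y, with the
#' independent-product variance.
#'
#' @param alpha_xi_xp,se_xi_xp single-trait couple MR estimate for X and its se.
#' @param alpha_x_y,se_x_y same-person MR estimate of X on Y and its se.
#' @return list with `gamma` and `se`.
#' @export
estimate_gamma <- function(alpha_xi_xp, se_xi_xp, alpha_x_y, se_x_y) {
  list(gamma = alpha_xi_xp * alpha_x_y,
       se = product_se(alpha_xi_xp, se_xi_xp, alpha_x_y, se_x_y))
}

#' Outcome-assortment path (rho)
#'
#' \eqn{\rho = \alpha_{y_i \to y_p | X_i} \cdot \alpha_{x \to y}}: the direct
#' couple effect on Y — the `Y_i` coefficient of the multivariable MR
#' `Y_p ~ Y_i + X_i`, which removes any residual index-to-partner effect of X —
#' times the within-person causal effect of X on Y.
#'
#' @param mvmr data.frame returned by [mvmr_estimate()] for `Y_p ~ Y_i + X_i`;
#'   the `Y_i` row is selected by `yi_name`.
#' @param alpha_x_y,se_x_y same-person MR estimate of X on Y and its se.
#' @param yi_name exposure label of the `Y_i` column (default `"Y_i"`).
#' @return list with `rho`, `se`, and `alpha_yi_yp` (the MVMR coefficient).
#' @export
estimate_rho <- function(mvmr, alpha_x_y, se_x_y, yi_name = "Y_i") {
  row <- mvmr[mvmr$exposure == yi_name, ]
  if (nrow(row) != 1) stop_invalid("MVMR result has no unique '", yi_name, "' row")
  list(rho = row$beta * alpha_x_y,
       se = product_se(row$beta, row$se, alpha_x_y, se_x_y),
       alpha_yi_yp = row$beta, se_yi_yp = row$se)
}

#' Residualize rho on gamma across trait pairs
#'
#' Ordinary least-squares residuals (with intercept) of `rho ~ gamma`; the
#' residualized rho is uncorrelated with gamma by construction, so the two
#' paths can enter a joint variance decomposition without double counting.
#'
#' @param rho,gamma numeric vectors over trait pairs (>= 3).
#' @return vector of residuals.
#' @export
residualize_rho <- function(rho, gamma) {
  if (length(rho) < 3 || length(gamma) != length(rho))
    stop_invalid("need >= 3 pairs of equal length")
  if (stats::sd(gamma) == 0) stop_invalid("degenerate regression: constant gamma")
  unname(stats::resid(stats::lm(rho ~ gamma)))
}

#' Compare the decomposed paths across trait pairs
#'
#' Given per-pair estimates of omega, gamma and rho (with ses), computes:
#' per-pair Z tests of rho vs gamma, omega vs gamma and omega vs rho; a paired
#' t test of |gamma| vs |rho| magnitudes after removing pairs whose gamma and
#' rho signs disagree; the through-origin regression of omega on gamma +
#' residualized rho with its uncentered R-squared (1 - RSS / sum(omega^2));
#' and a per-pair dominance category.
#'
#' @param paths data.frame with columns `pair`, `omega`, `se_omega`, `gamma`,
#'   `se_gamma`, `rho`, `se_rho`.
#' @return list with elements `paths` (input plus `rho_resid`, per-pair z/p
#'   columns and `category`), `paired_t` (htest for gamma vs rho), `n_sign_mismatch`,
#'   `origin_slope`, `origin_slope_se`, `r2_origin`, and `rho_gamma_cor`.
#' @export
compare_paths <- function(paths) {
  stopifnot(nrow(paths) >= 3)
  p <- paths
  zt <- function(a, sa, b, sb) (a - b) / sqrt(sa^2 + sb^2)
  p$z_rho_gamma <- zt(p$rho, p$se_rho, p$gamma, p$se_gamma)
  p$p_rho_gamma <- 2 * stats::pnorm(-abs(p$z_rho_gamma))
  p$z_omega_gamma <- zt(p$omega, p$se_omega, p$gamma, p$se_gamma)
  p$p_omega_gamma <- 2 * stats::pnorm(-abs(p$z_omega_gamma))
  p$z_omega_rho <- zt(p$omega, p$se_omega, p$rho, p$se_rho)
  p$p_omega_rho <- 2 * stats::pnorm(-abs(p$z_omega_rho))
  p$rho_resid <- residualize_rho(p$rho, p$gamma)
  p$category <- ifelse(abs(p$gamma) > abs(p$rho), "gamma_dominated", "rho_dominated")
  p$category[p$p_omega_gamma < 0.05 & p$p_omega_rho < 0.05 &
               abs(p$omega) > pmax(abs(p$gamma), abs(p$rho))] <- "unexplained"

  sign_ok <- sign(p$gamma) == sign(p$rho)
  d <- abs(p$gamma[sign_ok]) - abs(p$rho[sign_ok])
  paired_t <- if (length(d) >= 3) {
    if (stats::sd(d) == 0) {
      # identical magnitudes throughout: no evidence of a dominant path
      list(statistic = c(t = 0), p.value = 1, estimate = mean(d),
           parameter = c(df = length(d) - 1))
    } else stats::t.test(abs(p$gamma[sign_ok]), abs(p$rho[sign_ok]),
                         paired = TRUE)
  } else NULL

  fit <- stats::lm(omega ~ 0 + I(gamma + rho_resid), data = p)
  rss <- sum(stats::resid(fit)^2)
  r2 <- 1 - rss / sum(p$omega^2)  # uncentered: through-origin convention

  list(paths = p,
       paired_t = paired_t,
       n_sign_mismatch = sum(!sign_ok),
       origin_slope = unname(stats::coef(fit)[1]),
       origin_slope_se = unname(summary(fit)$coefficients[1, 2]),
       r2_origin = r2,
       rho_gamma_cor = stats::cor(p$rho, p$gamma))
}

#' Prune redundant trait pairs
#'
#' Two trait pairs (A, B) and (C, D) are redundant when
#' `max(|corr(A,C) * corr(B,D)|, |corr(A,D) * corr(B,C)|) > cap`; the pair with
#' the larger omega p-value is dropped (ties broken by pair id order).
#'
#' @param pairs data.frame with columns `pair`, `trait_x`, `trait_y`,
#'   `p_omega`.
#' @param corr_matrix phenotypic trait correlation matrix (dimnames = traits).
#' @param cap redundancy threshold (default 0.8).
#' @return the retained rows of `pairs`.
#' @export
prune_trait_pairs <- function(pairs, corr_matrix, cap = 0.8) {
  ord <- order(pairs$p_omega, pairs$pair)
  pr <- pairs[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(pr))
  for (i in seq_len(nrow(pr))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      r1 <- corr_matrix[pr$trait_x[i], pr$trait_x[j]] * corr_matrix[pr$trait_y[i], pr$trait_y[j]]
      r2 <- corr_matrix[pr$trait_x[i], pr$trait_y[j]] * corr_matrix[pr$trait_y[i], pr$trait_x[j]]
      if (max(abs(r1), abs(r2)) > cap) { keep[i] <- FALSE; break }
    }
  }
  out <- pr[keep, , drop = FALSE]
  out[order(match(out$pair, pairs$pair)), , drop = FALSE]
}
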