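#' Couple correlation induced by a confounder trait
#'
#' A trait Y that causally affects the focal trait X within a person and is
#' itself correlated across partners induces a couple correlation in X of
#' \eqn{C = \alpha_{y \to x}^2 \times \alpha_{y_i \to y_p}}. The sign of C is
#' the sign of the within-couple effect (negative confounders reduce couple
#' similarity).
#'
#' @param alpha_y_to_x within-person causal effect of Y on X.
#' @param alpha_yi_to_yp cross-partner causal effect of Y (couple effect).
#' @return the induced couple correlation C.
#' @export
confounding_correlation <- function(alpha_y_to_x, alpha_yi_to_yp) {
  alpha_y_to_x^2 * alpha_yi_to_yp
}

#' Variance of the confounding correlation C
#'
#' Delta-style variance of \eqn{C = A \cdot B} with \eqn{A = \alpha_{y\to x}^2}
#' and \eqn{B = \alpha_{y_i \to y_p}}, treating the two estimates as
#' independent normals: \eqn{Var(A) = 4\mu^2\sigma^2 + 2\sigma^4},
#' \eqn{E(A) = \mu^2 + \sigma^2}, and the product rule
#' \eqn{Var(AB) = Var(A)Var(B) + Var(A)E(B)^2 + Var(B)E(A)^2}.
#'
#' @param alpha_y_to_x,se1 the within-person effect and its standard error.
#' @param alpha_yi_to_yp,se2 the couple effect and its standard error.
#' @return Var(C).
#' @export
confounding_variance <- function(alpha_y_to_x, se1, alpha_yi_to_yp, se2) {
  var_a <- 4 * alpha_y_to_x^2 * se1^2 + 2 * se1^4
  e_a <- alpha_y_to_x^2 + se1^2
  var_b <- se2^2
  var_a * var_b + var_a * alpha_yi_to_yp^2 + var_b * e_a^2
}

#' Scan candidate traits for confounders of a focal couple correlation
#'
#' Applies the three sequential filters of the confounder search to a table of
#' per-candidate MR results: (1) significant same-person causal effect on the
#' focal trait at `0.05 / meff`; (2) significant within-couple effect at
#' `0.05 / n_remaining` (Bonferroni over the candidates surviving filter 1);
#' (3) phenotypic correlation with the focal trait below `corr_cap` in absolute
#' value (near-duplicate traits are not confounders). Each candidate's C and
#' Var(C) are attached.
#'
#' @param candidates data.frame with one row per candidate trait and columns
#'   `trait`, `alpha_y_to_x`, `se_y_to_x`, `p_y_to_x`, `alpha_yi_to_yp`,
#'   `se_yi_to_yp`, `p_yi_to_yp`, `corr_with_x`.
#' @param meff effective number of tests for filter 1.
#' @param corr_cap near-duplicate cap (default 0.8).
#' @return the input annotated with `pass_effect`, `pass_couple`, `pass_corr`,
#'   `retained`, `C`, `var_C`.
#' @export
confounder_scan <- function(candidates, meff, corr_cap = 0.8) {
  cand <- candidates
  cand$pass_effect <- cand$p_y_to_x < 0.05 / meff
  n_rem <- sum(cand$pass_effect)
  cand$pass_couple <- cand$pass_effect &
    cand$p_yi_to_yp < 0.05 / max(n_rem, 1)
  cand$pass_corr <- abs(cand$corr_with_x) < corr_cap
  cand$retained <- cand$pass_effect & cand$pass_couple & cand$pass_corr
  cand$C <- confounding_correlation(cand$alpha_y_to_x, cand$alpha_yi_to_yp)
  cand$var_C <- confounding_variance(cand$alpha_y_to_x, cand$se_y_to_x,
                                     cand$alpha_yi_to_yp, cand$se_yi_to_yp)
  cand
}

#' Prune correlated confounders and sum their contributions
#'
#' Greedy pruning by descending |C| (ties broken by trait id): a confounder is
#' accepted only if its squared phenotypic correlation with every already
#' accepted confounder is below `r2_threshold`. The total confounding is
#' `C_sum = sum(C)` over the accepted set with `Var(C_sum) = sum(Var(C))`
#' (terms treated as uncorrelated after pruning).
#'
#' @param confounders data.frame with columns `trait`, `C`, `var_C`.
#' @param corr_matrix phenotypic correlation matrix covering all candidate
#'   traits (dimnames = trait ids).
#' @param r2_threshold squared-correlation pruning threshold (default 0.1).
#' @return list with `retained` (trait ids), `C_sum`, `var_C_sum`, `se_C_sum`.
#' @export
prune_confounders <- function(confounders, corr_matrix, r2_threshold = 0.1) {
  cf <- confounders[order(-abs(confounders$C), confounders$trait), , drop = FALSE]
  accepted <- character(0)
  for (i in seq_len(nrow(cf))) {
    id <- cf$trait[i]
    if (length(accepted) == 0 ||
        all(corr_matrix[id, accepted]^2 < r2_threshold))
      accepted <- c(accepted, id)
  }
  keep <- confounders$trait %in% accepted
  list(retained = confounders$trait[keep],
       C_sum = sum(confounders$C[keep]),
       var_C_sum = sum(confounders$var_C[keep]),
       se_C_sum = sqrt(sum(confounders$var_C[keep])))
}

#' Ratio of confounding-induced to raw couple correlation
#'
#' @param C confounding correlation (sum the C values first for composite
#'   confounders such as paired birthplace coordinates).
#' @param couple_r raw phenotypic couple correlation (nonzero).
#' @return `C / couple_r`.
#' @export
confounding_ratio <- function(C, couple_r) {
  if (any(couple_r == 0))
    stop(structure(class = c("couplemr_undefined_ratio", "error", "condition"),
                   list(message = "couple correlation is zero: ratio undefined",
                        call = sys.call())))
  C / couple_r
}
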