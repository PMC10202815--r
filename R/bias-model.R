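#' Parameters for the analytic bias model
#'
#' The closed-form expectations of the cross-partner MR estimator under the
#' structural couple model. Defaults follow the reference setting: direct trait
#' assortment `r_x = 0.2` and heritability 20% (`g = sqrt(0.2)`,
#' `e = sqrt(0.8)`), all violation parameters zero.
#'
#' @inheritParams couple_model_params
#' @return an object of class `bias_params`.
#' @export
bias_params <- function(h2 = 0.2, g = sqrt(h2), e = sqrt(1 - g^2),
                        r_g = 0, r_e = 0, r_x = 0.2,
                        s_g = 0, s_e = 0, s_x = 0) {
  if (g^2 > 1) stop_invalid("g^2 must not exceed 1")
  structure(list(g = g, e = e, r_g = r_g, r_e = r_e, r_x = r_x,
                 s_g = s_g, s_e = s_e, s_x = s_x),
            class = "bias_params")
}

# the recurring parental-path term: induced cor(G_O, E_O)
parental_term <- function(p) (p$s_g + p$g * p$s_x) / sqrt(2)

#' Expected effect of the index genotype on the index trait
#'
#' \eqn{E[\hat\beta_{G^i \to X^i}] = g + \frac{1}{\sqrt2}(s_G + g s_X) e}:
#' the direct genetic path plus the genotype-environment correlation induced by
#' parental effects. Note that `s_e` does not enter (parental environment opens
#' no path from offspring genotype to offspring environment).
#'
#' @param p a [bias_params()] object.
#' @return the expectation.
#' @export
expected_beta_index <- function(p) {
  stopifnot(inherits(p, "bias_params"))
  p$g + parental_term(p) * p$e
}

#' Expected effect of the index genotype on the partner's trait
#'
#' \eqn{E[\hat\beta_{G^i \to X^p}] = (g + \frac{1}{\sqrt2}(s_G + g s_X) e) r_X
#'   + r_G g + \frac{1}{\sqrt2}(s_G + g s_X)(r_E e)}: the genotype's effect on
#' the own trait propagated through direct trait assortment, plus leakage
#' through genotype assortment and through environment assortment via the
#' parental path.
#'
#' @param p a [bias_params()] object.
#' @return the expectation.
#' @export
expected_beta_partner <- function(p) {
  stopifnot(inherits(p, "bias_params"))
  t <- parental_term(p)
  (p$g + t * p$e) * p$r_x + p$r_g * p$g + t * (p$r_e * p$e)
}

#' Expected cross-partner MR estimate and its bias
#'
#' The ratio of the two genotype-effect expectations:
#' \deqn{E[\hat\alpha] \approx r_X + \frac{r_G g + \frac{1}{\sqrt2}(s_G + g
#' s_X)(r_E e)}{g + \frac{1}{\sqrt2}(s_G + g s_X) e}} with bias
#' \eqn{E[\hat\alpha] - r_X}. Absent violations (`r_g = r_e = s_g = s_x = 0`)
#' the estimator is unbiased for the direct trait assortment `r_x`.
#'
#' @param p a [bias_params()] object.
#' @return list with `expectation` and `bias`.
#' @export
expected_mr <- function(p) {
  stopifnot(inherits(p, "bias_params"))
  denom <- expected_beta_index(p)
  if (abs(denom) < .Machine$double.eps^0.5)
    stop(structure(class = c("couplemr_undefined_expectation", "error", "condition"),
                   list(message = "expected genotype-trait effect is zero: MR expectation undefined",
                        call = sys.call())))
  expectation <- expected_beta_partner(p) / denom
  list(expectation = expectation, bias = expectation - p$r_x)
}

#' Expected couple correlations of trait, environment and genetic score
#'
#' The three additive closed forms: \eqn{cor(X_i, X_p) = r_X + r_E e^2 + r_G
#' g^2}; \eqn{cor(E_i, E_p) = r_E + r_X e^2 + r_G t^2}; \eqn{cor(G_i, G_p) =
#' r_G + r_X g^2 + r_E t^2}, with \eqn{t = \frac{1}{\sqrt2}(s_G + g s_X)} the
#' parental genotype-environment term.
#'
#' @param p a [bias_params()] object.
#' @return list with `corr_x`, `corr_e`, `corr_g`.
#' @export
expected_couple_correlations <- function(p) {
  stopifnot(inherits(p, "bias_params"))
  t <- parental_term(p)
  list(corr_x = p$r_x + p$r_e * p$e^2 + p$r_g * p$g^2,
       corr_e = p$r_e + p$r_x * p$e^2 + p$r_g * t^2,
       corr_g = p$r_g + p$r_x * p$g^2 + p$r_e * t^2)
}

#' Typical violation magnitudes induced by a genetically correlated trait
#'
#' When assortment or parental effects act on a secondary trait Y genetically
#' correlated with X, the induced violations on X have typical sizes
#' \eqn{r_G = (g \, r_G(X,Y))^2 r_Y} and \eqn{s_G = g \, r_G(X,Y) \, s_Y}.
#'
#' @param g genetic effect on the focal trait.
#' @param r_gxy genetic correlation between X and Y (|r| <= 1).
#' @param r_y direct assortment on Y.
#' @param s_y parental effect of Y.
#' @return list with `r_g` and `s_g`.
#' @export
derived_violation_params <- function(g, r_gxy, r_y, s_y) {
  check_corr(r_gxy, "r_gxy")
  list(r_g = (g * r_gxy)^2 * r_y, s_g = g * r_gxy * s_y)
}

#' Bias of the cross-partner MR estimator over a parameter grid
#'
#' Varies two of the violation parameters over dense ranges with the others
#' fixed at `base`, evaluating [expected_mr()] at every grid point.
#'
#' @param base a [bias_params()] object (the fixed parameters).
#' @param vary character vector of two parameter names among
#'   `c("r_g", "r_e", "s_g", "s_x")`.
#' @param ranges list of two length-2 numeric ranges, one per varied parameter.
#' @param resolution grid points per axis (default 41).
#' @return long-format data.frame with the two varied parameters, `expectation`
#'   and `bias`.
#' @export
bias_grid <- function(base, vary, ranges, resolution = 41) {
  valid <- c("r_g", "r_e", "s_g", "s_x")
  if (length(vary) != 2 || !all(vary %in% valid))
    stop_invalid("vary must name two of: ", paste(valid, collapse = ", "))
  ax <- lapply(ranges, function(r) seq(r[1], r[2], length.out = resolution))
  grid <- expand.grid(ax[[1]], ax[[2]])
  names(grid) <- vary
  res <- apply(grid, 1, function(row) {
    p <- base
    p[[vary[1]]] <- row[[1]]
    p[[vary[2]]] <- row[[2]]
    unlist(expected_mr(p))
  })
  grid$expectation <- res["expectation", ]
  grid$bias <- res["bias", ]
  grid
}
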