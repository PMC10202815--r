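#' Parameters of a two-trait couple network
#'
#' Extends the single-trait couple model to two polygenic traits per person
#' with a within-person causal link, so cross-trait cross-partner paths can be
#' simulated. At most one of `alpha_x_to_y` (X causes Y; the path-decomposition
#' setting) and `alpha_y_to_x` (Y causes X; the confounder setting) may be
#' nonzero. Couples form by direct assortment on the realized traits with
#' coefficients `r_x` and `r_y`; `direct_xi_to_yp` injects an extra direct
#' effect of the index person's X on the partner's Y (a "secondhand smoke"
#' mechanism) after couple formation, without rescaling.
#'
#' @param n_couples number of couples.
#' @param n_snps_x,n_snps_y loci behind each trait's genetic score (disjoint sets).
#' @param maf effect-allele frequency.
#' @param h2_x,h2_y trait heritabilities.
#' @param alpha_x_to_y within-person causal effect of X on Y (|alpha| < 1).
#' @param alpha_y_to_x within-person causal effect of Y on X (|alpha| < 1).
#' @param r_x,r_y direct couple assortment on trait X and trait Y.
#' @param direct_xi_to_yp direct cross-partner effect added as
#'   `Y_p <- Y_p + direct_xi_to_yp * X_i`.
#' @param seed integer seed.
#' @return an object of class `trait_network_params`.
#' @export
trait_network_params <- function(n_couples, n_snps_x = 100, n_snps_y = 100,
                                 maf = 0.5, h2_x = 0.2, h2_y = 0.2,
                                 alpha_x_to_y = 0, alpha_y_to_x = 0,
                                 r_x = 0, r_y = 0, direct_xi_to_yp = 0,
                                 seed = NULL) {
  if (abs(alpha_x_to_y) >= 1 || abs(alpha_y_to_x) >= 1)
    stop_invalid("within-person causal effects must satisfy |alpha| < 1")
  if (alpha_x_to_y != 0 && alpha_y_to_x != 0)
    stop_invalid("only one within-person causal direction may be nonzero")
  check_corr(r_x, "r_x"); check_corr(r_y, "r_y")
  if (abs(r_x) + abs(r_y) > 1)
    stop_infeasible("sum of |direct assortment coefficients| exceeds 1")
  check_prob(maf, "maf")
  structure(list(n_couples = as.integer(n_couples),
                 n_snps_x = as.integer(n_snps_x), n_snps_y = as.integer(n_snps_y),
                 maf = maf, h2_x = h2_x, h2_y = h2_y,
                 alpha_x_to_y = alpha_x_to_y, alpha_y_to_x = alpha_y_to_x,
                 r_x = r_x, r_y = r_y, direct_xi_to_yp = direct_xi_to_yp,
                 seed = seed),
            class = "trait_network_params")
}

network_side <- function(p) {
  n <- p$n_couples
  gx <- sqrt(p$h2_x); ex <- sqrt(1 - p$h2_x)
  gy <- sqrt(p$h2_y); ey <- sqrt(1 - p$h2_y)
  px <- new_persons(n, p$n_snps_x, rep(p$maf, p$n_snps_x), gx, ex)
  py <- new_persons(n, p$n_snps_y, rep(p$maf, p$n_snps_y), gy, ey)
  if (p$alpha_y_to_x != 0) {
    Y <- py$X
    X <- p$alpha_y_to_x * Y + sqrt(1 - p$alpha_y_to_x^2) * px$X
  } else {
    X <- px$X
    Y <- p$alpha_x_to_y * X + sqrt(1 - p$alpha_x_to_y^2) * py$X
  }
  geno <- cbind(px$geno, py$geno)
  colnames(geno) <- c(paste0("x_snp", seq_len(p$n_snps_x)),
                      paste0("y_snp", seq_len(p$n_snps_y)))
  list(geno = geno, G_x = px$G, G_y = py$G, X = X, Y = Y)
}

#' Simulate a two-trait couple cohort with a within-person causal network
#'
#' @param params a [trait_network_params()] object.
#' @return a `couple_cohort` whose `index`/`partner` elements carry traits `X`
#'   and `Y`, trait-specific genetic scores `G_x`, `G_y`, and a combined
#'   genotype matrix; `snps` records which trait each locus belongs to.
#' @export
simulate_trait_network <- function(params) {
  stopifnot(inherits(params, "trait_network_params"))
  p <- params
  with_seed(p$seed, {
    n <- p$n_couples
    index <- network_side(p)
    partner <- network_side(p)
    perm <- pair_by_channels(cbind(index$X, index$Y),
                             cbind(partner$X, partner$Y),
                             c(p$r_x, p$r_y))
    partner <- lapply(partner, function(v)
      if (is.matrix(v)) v[perm, , drop = FALSE] else v[perm])
    if (p$direct_xi_to_yp != 0)
      partner$Y <- partner$Y + p$direct_xi_to_yp * index$X

    sex_i <- sample(c("M", "F"), n, replace = TRUE)
    index$sex <- sex_i; partner$sex <- ifelse(sex_i == "M", "F", "M")
    age <- round(pmin(pmax(stats::rnorm(n, 58, 8), 35), 75))
    index$age <- age; partner$age <- age
    tt <- pmax(round(0.5 * (age - 30) + stats::rnorm(n, 0, 5)), 0)
    index$time_at_address <- partner$time_at_address <- tt

    k <- ncol(index$geno)
    bases <- c("A", "C", "G", "T")
    ea <- sample(bases, k, replace = TRUE)
    oa <- vapply(ea, function(b) sample(setdiff(bases, c(b, chartr("ACGT", "TGCA", b))), 1),
                 character(1))
    structure(list(params = p, index = index, partner = partner,
                   snps = data.frame(snp = colnames(index$geno),
                                     trait = rep(c("X", "Y"), c(p$n_snps_x, p$n_snps_y)),
                                     effect_allele = ea, other_allele = oa,
                                     stringsAsFactors = FALSE),
                   couples = data.frame(household_id = seq_len(n),
                                        age_median = age, time_together = tt)),
              class = "couple_cohort")
  })
}

#' Instrument SNP ids for a trait in a network cohort
#' @param cohort a two-trait `couple_cohort`.
#' @param trait `"X"` or `"Y"`.
#' @return character vector of SNP ids belonging to the trait's score.
#' @export
trait_snps <- function(cohort, trait) {
  if (is.null(cohort$snps$trait)) return(cohort$snps$snp)
  cohort$snps$snp[cohort$snps$trait == trait]
}
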