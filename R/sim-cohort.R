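#' Parameters of the structural couple model
#'
#' Bundles all parameters of the generative model behind the cross-partner MR
#' analyses. A person's trait is \eqn{X = g G + e E} with standardized genetic
#' score \eqn{G} and environment \eqn{E}; the offspring environment receives
#' parental contributions \eqn{s_G G_P + s_E E_P + s_X X_P} from the rescaled
#' mean parental score, environment and trait; couples form under simultaneous
#' direct assortment on \eqn{G}, \eqn{E} and \eqn{X} with coefficients
#' `r_g`, `r_e`, `r_x`.
#'
#' @param n_couples number of couples to simulate.
#' @param n_snps number of unlinked causal loci behind the genetic score.
#' @param maf effect-allele frequency (scalar or per-SNP).
#' @param h2 trait heritability; sets `g = sqrt(h2)`, `e = sqrt(1 - h2)` unless
#'   `g`/`e` are given explicitly.
#' @param g,e direct genetic and environmental path coefficients; must satisfy
#'   `g^2 + e^2 = 1` so the trait has unit variance absent parental effects.
#' @param r_g,r_e,r_x direct cross-partner assortment coefficients on genetic
#'   score, environment and trait.
#' @param s_g,s_e,s_x parental effects of mean parental genetic score,
#'   environment and trait on the offspring environment.
#' @param convergence_slope optional per-year drift of the direct trait
#'   assortment with time spent together (0 = couples do not converge).
#' @param ld_rho optional AR(1) LD between adjacent loci.
#' @param seed integer seed for the whole cohort draw.
#' @return an object of class `couple_model_params` (a validated list).
#' @export
couple_model_params <- function(n_couples, n_snps = 100, maf = 0.5,
                                h2 = 0.2, g = sqrt(h2), e = sqrt(1 - g^2),
                                r_g = 0, r_e = 0, r_x = 0,
                                s_g = 0, s_e = 0, s_x = 0,
                                convergence_slope = 0, ld_rho = 0, seed = NULL) {
  if (!is.numeric(n_couples) || n_couples < 2) stop_invalid("n_couples must be >= 2")
  if (!is.numeric(n_snps) || n_snps < 1) stop_invalid("n_snps must be >= 1")
  check_prob(maf, "maf")
  if (abs(g^2 + e^2 - 1) > 1e-8)
    stop_invalid("g^2 + e^2 must equal 1 (unit trait variance without parental effects)")
  for (nm in c("r_g", "r_e", "r_x")) check_corr(get(nm), nm)
  total <- r_x + r_e * e^2 + r_g * g^2
  if (abs(total) > 1)
    stop_infeasible("implied total couple correlation ", signif(total, 4),
                    " is not a valid correlation")
  if (sum(abs(c(r_g, r_e, r_x))) > 1)
    stop_infeasible("sum of |direct assortment coefficients| exceeds 1")
  structure(list(n_couples = as.integer(n_couples), n_snps = as.integer(n_snps),
                 maf = maf, g = g, e = e,
                 r_g = r_g, r_e = r_e, r_x = r_x,
                 s_g = s_g, s_e = s_e, s_x = s_x,
                 convergence_slope = convergence_slope,
                 ld_rho = ld_rho, seed = seed),
            class = "couple_model_params")
}

# one generation of unrelated persons: genotypes, scores, environments, trait
new_persons <- function(n, k, maf, g, e, ld_rho = 0) {
  geno <- simulate_genotypes(n, k, maf, ld_rho = ld_rho)
  G <- genetic_score(geno, if (length(maf) == 1L) rep(maf, k) else maf)
  E <- stats::rnorm(n)
  list(geno = geno, G = G, E = E, X = g * G + e * E)
}

# rescaled mean of a maternal/paternal pair: unit variance by construction
parental_aggregate <- function(vm, vf) {
  (vm + vf) / sqrt(2 * (1 + stats::cor(vm, vf)))
}

# one side of the cohort (index or partner): parents, Mendelian offspring,
# parental effects on the offspring environment
simulate_side <- function(p) {
  n <- p$n_couples; k <- p$n_snps
  maf <- if (length(p$maf) == 1L) rep(p$maf, k) else p$maf
  mum <- new_persons(n, k, maf, p$g, p$e, p$ld_rho)
  dad <- new_persons(n, k, maf, p$g, p$e, p$ld_rho)
  perm <- pair_by_channels(cbind(mum$G, mum$E, mum$X),
                           cbind(dad$G, dad$E, dad$X),
                           c(p$r_g, p$r_e, p$r_x))
  dad <- lapply(dad, function(v) if (is.matrix(v)) v[perm, , drop = FALSE] else v[perm])
  geno_o <- mendelian_offspring(mum$geno, dad$geno)
  G_O <- genetic_score(geno_o, maf)
  G_P <- parental_aggregate(mum$G, dad$G)
  E_P <- parental_aggregate(mum$E, dad$E)
  X_P <- parental_aggregate(mum$X, dad$X)
  det <- p$s_g * G_P + p$s_e * E_P + p$s_x * X_P
  v_det <- stats::var(det)
  if (v_det > 1)
    stop_infeasible("parental effects explain more than the whole environmental variance")
  E_O <- det + sqrt(1 - v_det) * stats::rnorm(n)
  list(geno = geno_o, G = G_O, E = E_O, X = p$g * G_O + p$e * E_O,
       G_P = G_P, E_P = E_P, X_P = X_P)
}

#' Simulate a couple cohort under the structural assortment model
#'
#' Generates index and partner sides independently (each with its own assorted
#' parental generation, Mendelian genotype transmission and parental effects on
#' the offspring environment) and then forms couples by a mixture of
#' single-variable assortment channels so that each direct assortment
#' coefficient contributes its own additive term to the cross-partner
#' covariance. In expectation the realized correlations follow the model's
#' closed forms, e.g. \eqn{cor(X_i, X_p) \approx r_X + r_E e^2 + r_G g^2}.
#'
#' @param params a [couple_model_params()] object.
#' @return an object of class `couple_cohort`: a list with elements `params`,
#'   `index` and `partner` (each holding `geno`, `G`, `E`, `X`, parental
#'   aggregates `G_P`, `E_P`, `X_P`, `sex`, `age`, `time_at_address`),
#'   `snps` (id / effect and other allele), and `couples` (household id,
#'   median age, time together).
#' @export
simulate_couple_cohort <- function(params) {
  stopifnot(inherits(params, "couple_model_params"))
  p <- params
  with_seed(p$seed, {
    n <- p$n_couples
    index <- simulate_side(p)
    partner <- simulate_side(p)

    # demographics first: couple ages and a time-together proxy, so that a
    # convergence drift can act on the pairing strength within time strata
    age <- round(pmin(pmax(stats::rnorm(n, 58, 8), 35), 75))
    time_together <- pmax(round(0.5 * (age - 30) + stats::rnorm(n, 0, 5)), 0)

    r <- c(p$r_g, p$r_e, p$r_x)
    vi <- cbind(index$G, index$E, index$X)
    vp <- cbind(partner$G, partner$E, partner$X)
    if (p$convergence_slope == 0) {
      perm <- pair_by_channels(vi, vp, r)
    } else {
      # stratify by time together; let direct trait assortment drift linearly
      bins <- bin_couples(time_together, n_bins = 5)
      centre0 <- stats::median(time_together)
      perm <- integer(n)
      for (b in seq_along(bins$medians)) {
        idx <- which(bins$bin == b)
        rb <- r
        rb[3] <- min(max(r[3] + p$convergence_slope * (bins$medians[b] - centre0), -1), 1)
        perm[idx] <- idx[pair_by_channels(vi[idx, , drop = FALSE],
                                          vp[idx, , drop = FALSE], rb)]
      }
    }
    partner <- lapply(partner, function(v)
      if (is.matrix(v)) v[perm, , drop = FALSE] else v[perm])

    sex_i <- sample(c("M", "F"), n, replace = TRUE)
    index$sex <- sex_i
    partner$sex <- ifelse(sex_i == "M", "F", "M")
    jitter_i <- sample(-2:2, n, replace = TRUE)
    index$age <- age + jitter_i
    partner$age <- age - jitter_i
    index$time_at_address <- time_together + sample(0:2, n, replace = TRUE)
    partner$time_at_address <- time_together + sample(0:2, n, replace = TRUE)

    bases <- c("A", "C", "G", "T")
    ea <- sample(bases, p$n_snps, replace = TRUE)
    oa <- vapply(ea, function(b) sample(setdiff(bases, c(b, chartr("ACGT", "TGCA", b))), 1),
                 character(1))
    structure(list(params = p,
                   index = index, partner = partner,
                   snps = data.frame(snp = colnames(index$geno),
                                     effect_allele = ea, other_allele = oa,
                                     stringsAsFactors = FALSE),
                   couples = data.frame(household_id = seq_len(n),
                                        age_median = age,
                                        time_together = time_together)),
              class = "couple_cohort")
  })
}

#' Couple-level trait table
#'
#' One row per couple with the focal trait of both members and the couple-level
#' binning variables used by the convergence analyses.
#'
#' @param cohort a `couple_cohort` (or two-trait network cohort).
#' @param trait trait name; `"X"` for single-trait cohorts.
#' @return data.frame with columns `household_id`, `x_i`, `x_p`, `sex_i`,
#'   `age_median`, `time_together`.
#' @export
couple_table <- function(cohort, trait = "X") {
  stopifnot(inherits(cohort, "couple_cohort"))
  xi <- cohort$index[[trait]]; xp <- cohort$partner[[trait]]
  if (is.null(xi)) stop_invalid("trait '", trait, "' not present in cohort")
  data.frame(household_id = cohort$couples$household_id,
             x_i = xi, x_p = xp,
             sex_i = cohort$index$sex,
             age_median = cohort$couples$age_median,
             time_together = cohort$couples$time_together)
}

#' @export
print.couple_cohort <- function(x, ...) {
  traits <- intersect(c("X", "Y"), names(x$index))
  cat("couple_cohort:", nrow(x$couples), "couples,",
      nrow(x$snps), "SNPs, traits:", paste(traits, collapse = ", "), "\n")
  for (tr in traits)
    cat(sprintf("  cor(%s_i, %s_p) = %.3f\n", tr, tr,
                stats::cor(x$index[[tr]], x$partner[[tr]])))
  invisible(x)
}
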