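#' Emulate GWAS summary statistics from a simulated cohort
#'
#' Runs a per-SNP linear regression of a (standardized) phenotype on genotype
#' dosage, mirroring how biobank-scale summary statistics are produced. The
#' genotypes are always taken from the index member of each couple — this is
#' the cross-partner design: with `person = "index"` the result is an ordinary
#' same-person GWAS, with `person = "partner"` the dependent variable is the
#' partner's phenotype regressed on the index genotype.
#'
#' @param cohort a `couple_cohort`.
#' @param trait trait name (`"X"`, or `"Y"` for network cohorts).
#' @param person whose phenotype is the dependent variable: `"index"` or
#'   `"partner"`.
#' @param covariates optional numeric matrix (one row per couple) of covariates
#'   to adjust both genotype and phenotype for (e.g. age).
#' @param sex optional `"M"`/`"F"`: restrict to couples whose index member has
#'   that sex (sex-specific summary statistics).
#' @param snps optional character vector of SNP ids to test (default: all).
#' @return data.frame with columns `snp`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `n`, `pval`. SNPs whose genotype is constant in the analysis
#'   sample are excluded and recorded in `attr(, "excluded")`.
#' @export
emulate_gwas_summary <- function(cohort, trait = "X", person = c("partner", "index"),
                                 covariates = NULL, sex = NULL, snps = NULL) {
  stopifnot(inherits(cohort, "couple_cohort"))
  person <- match.arg(person)
  pheno <- cohort[[person]][[trait]]
  if (is.null(pheno)) stop_invalid("trait '", trait, "' not present in cohort")
  keep <- rep(TRUE, length(pheno))
  if (!is.null(sex)) keep <- cohort$index$sex == sex
  if (sum(keep) < 30) stop_invalid("fewer than 30 couples in the analysis sample")
  geno <- cohort$index$geno
  if (!is.null(snps)) geno <- geno[, snps, drop = FALSE]
  g <- geno[keep, , drop = FALSE]
  y <- zscale(pheno[keep])
  n <- length(y)
  ncov <- 0L
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)[keep, , drop = FALSE]
    qrc <- qr(cbind(1, cv))
    y <- qr.resid(qrc, y)
    g <- qr.resid(qrc, g)
    ncov <- ncol(cv)
  }
  gc_ <- sweep(g, 2, colMeans(g))
  yc <- y - mean(y)
  sxx <- colSums(gc_^2)
  ok <- sxx > 0
  if (!all(ok)) warning(sum(!ok), " SNP(s) with constant genotype excluded")
  sxy <- drop(crossprod(gc_[, ok, drop = FALSE], yc))
  sxx <- sxx[ok]
  beta <- sxy / sxx
  rss <- sum(yc^2) - beta * sxy
  df <- n - 2L - ncov
  se <- sqrt(pmax(rss, 0) / df / sxx)
  z <- beta / se
  out <- data.frame(snp = colnames(g)[ok],
                    beta = beta, se = se, n = n,
                    pval = 2 * stats::pnorm(-abs(z)),
                    stringsAsFactors = FALSE, row.names = NULL)
  al <- cohort$snps[match(out$snp, cohort$snps$snp), c("effect_allele", "other_allele")]
  out <- cbind(out["snp"], al, out[c("beta", "se", "n", "pval")])
  row.names(out) <- NULL
  attr(out, "excluded") <- colnames(g)[!ok]
  out
}

#' Fixed-effect meta-analysis of sex-specific summary statistics at SNP level
#'
#' Convenience wrapper: computes male- and female-index summary statistics and
#' pools them per SNP with [meta_fixed()] before any MR, which is how the
#' sex-combined analyses are built (pooling at the SNP level rather than
#' meta-analysing MR estimates minimizes weak-instrument bias).
#'
#' @inheritParams emulate_gwas_summary
#' @return summary-statistics data.frame as [emulate_gwas_summary()], pooled
#'   across sexes (`n` is the summed sample size).
#' @export
emulate_gwas_sex_meta <- function(cohort, trait = "X", person = c("partner", "index"),
                                  covariates = NULL, snps = NULL) {
  person <- match.arg(person)
  sm <- emulate_gwas_summary(cohort, trait, person, covariates, sex = "M", snps = snps)
  sf <- emulate_gwas_summary(cohort, trait, person, covariates, sex = "F", snps = snps)
  common <- intersect(sm$snp, sf$snp)
  sm <- sm[match(common, sm$snp), ]; sf <- sf[match(common, sf$snp), ]
  pooled <- meta_fixed(sm$beta, sm$se, sf$beta, sf$se)
  z <- pooled$beta / pooled$se
  data.frame(snp = common,
             effect_allele = sm$effect_allele, other_allele = sm$other_allele,
             beta = pooled$beta, se = pooled$se, n = sm$n + sf$n,
             pval = 2 * stats::pnorm(-abs(z)),
             stringsAsFactors = FALSE, row.names = NULL)
}
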