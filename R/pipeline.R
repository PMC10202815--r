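#' Identify couples from a household table
#'
#' Retains households with exactly two unrelated, opposite-sex members where
#' both report living with their spouse/partner, mirroring biobank couple
#' definitions.
#'
#' @param households data.frame with one row per person and columns
#'   `person_id`, `household_id`, `sex` (`"M"`/`"F"`), `related` (logical: the
#'   person is genetically related to another household member), and
#'   `relationship` (self-reported; couples require the value `"partner"`).
#' @return data.frame with one row per retained couple (`household_id`,
#'   `person_1`, `person_2`); `attr(, "exclusions")` counts households dropped
#'   by each rule, applied sequentially.
#' @export
identify_couples <- function(households) {
  req <- c("person_id", "household_id", "sex", "related", "relationship")
  missing_cols <- setdiff(req, names(households))
  if (length(missing_cols))
    stop_invalid("missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(households$person_id))
    stop_invalid("duplicated person_id: input integrity violated")
  sp <- split(households, households$household_id)
  size2 <- vapply(sp, nrow, integer(1)) == 2L
  opp <- vapply(sp, function(h) nrow(h) == 2L && h$sex[1] != h$sex[2], logical(1))
  unrel <- vapply(sp, function(h) !any(h$related), logical(1))
  partn <- vapply(sp, function(h) all(h$relationship == "partner"), logical(1))
  keep <- size2 & opp & unrel & partn
  excl <- c(not_two_members = sum(!size2),
            same_sex = sum(size2 & !opp),
            related = sum(size2 & opp & !unrel),
            not_partner_coded = sum(size2 & opp & unrel & !partn))
  out <- do.call(rbind, lapply(sp[keep], function(h)
    data.frame(household_id = h$household_id[1],
               person_1 = h$person_id[1], person_2 = h$person_id[2],
               stringsAsFactors = FALSE)))
  if (is.null(out))
    out <- data.frame(household_id = character(0), person_1 = character(0),
                      person_2 = character(0))
  row.names(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' Rank-preserving inverse normal quantile transformation
#'
#' Maps values to normal quantiles of their (Blom-offset) rank positions,
#' `qnorm((rank - 3/8) / (n + 1/4))`; ties receive the average rank and missing
#' values are preserved.
#'
#' @param values numeric vector with at least 3 distinct non-missing values.
#' @return transformed vector, same length and missingness as the input.
#' @export
inverse_normal_transform <- function(values) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 3) stop_invalid("need at least 3 non-missing values")
  if (length(unique(x)) < 2) stop_invalid("degenerate input: all values identical")
  r <- rank(x, ties.method = "average")
  out <- values
  out[ok] <- stats::qnorm((r - 0.375) / (length(x) + 0.25))
  out
}

#' Couple trait correlation
#'
#' Pairwise-complete Pearson correlation between the index and partner values
#' of a trait, with standard error `sqrt((1 - r^2) / (n - 2))`, plus the
#' Spearman correlation as a rank-based robustness companion.
#'
#' @param x_i,x_p trait values of the index person and partner.
#' @return list with `r`, `se`, `spearman`, `n`.
#' @export
couple_correlation <- function(x_i, x_p) {
  ok <- stats::complete.cases(x_i, x_p)
  n <- sum(ok)
  if (n < 4) stop_invalid("need at least 4 complete pairs")
  if (stats::sd(x_i[ok]) == 0 || stats::sd(x_p[ok]) == 0)
    stop_invalid("degenerate input: zero variance")
  r <- stats::cor(x_i[ok], x_p[ok])
  list(r = r, se = sqrt((1 - r^2) / (n - 2)),
       spearman = stats::cor(x_i[ok], x_p[ok], method = "spearman"), n = n)
}

#' Screen traits on couple correlation and instrument availability
#'
#' @param traits data.frame with columns `trait`, `r` (couple Pearson
#'   correlation) and `n_valid_ivs`.
#' @param corr_threshold minimum couple correlation (default 0.1, exclusive).
#' @param min_ivs minimum number of valid instruments (default 5).
#' @return the input with logical `retained` and a `reason` code
#'   (`"ok"`, `"low_correlation"`, `"too_few_ivs"`).
#' @export
screen_traits <- function(traits, corr_threshold = 0.1, min_ivs = 5) {
  low_r <- traits$r <= corr_threshold
  few <- traits$n_valid_ivs < min_ivs
  traits$retained <- !low_r & !few
  traits$reason <- ifelse(low_r, "low_correlation",
                          ifelse(few, "too_few_ivs", "ok"))
  traits
}

#' Effective number of independent tests among correlated traits
#'
#' Li-Ji eigenvalue estimator on the absolute trait correlation matrix:
#' \eqn{M_{eff} = \sum_i [ I(\lambda_i \ge 1) + (\lambda_i - \lfloor \lambda_i
#' \rfloor) ]}. Equals m for independent traits and 1 when all traits are
#' perfectly correlated.
#'
#' @param corr_matrix symmetric trait correlation matrix with unit diagonal.
#' @return the effective number of tests (in `[1, m]`).
#' @export
effective_tests <- function(corr_matrix) {
  m <- nrow(corr_matrix)
  if (m != ncol(corr_matrix) || !isTRUE(all.equal(unname(diag(corr_matrix)), rep(1, m))))
    stop_invalid("corr_matrix must be square with unit diagonal")
  ev <- eigen(abs(corr_matrix), symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) {
    warning("correlation matrix not positive semi-definite; clipping eigenvalues at 0")
  }
  # guard the floor() against eigenvalues like 2 - 1e-15
  ev <- round(pmax(ev, 0), 8)
  sum(ifelse(ev >= 1, 1, 0) + (ev - floor(ev)))
}

#' Cross-partner MR from exposure and outcome summary statistics
#'
#' The summary-level core shared by the single- and cross-trait couple MR:
#' harmonizes by SNP id, optionally applies the Steiger directionality filter,
#' standardizes both sides to the correlation scale, and runs IVW.
#'
#' @param exp_stats exposure summary statistics (`snp`, `beta`, `se`, `n`,
#'   `pval`).
#' @param out_stats outcome summary statistics for the same SNPs.
#' @param steiger_p one-tailed Steiger threshold, or `NULL` to skip the filter.
#' @param min_ivs minimum surviving instruments; fewer raises a screen-failure
#'   error.
#' @return an `mr_estimate` (standardized scale) with attribute `n_ivs`.
#' @export
couple_mr_from_stats <- function(exp_stats, out_stats, steiger_p = NULL, min_ivs = 5) {
  common <- intersect(exp_stats$snp, out_stats$snp)
  ex <- exp_stats[match(common, exp_stats$snp), ]
  ou <- out_stats[match(common, out_stats$snp), ]
  es <- standardize_effects(ex$beta, ex$se, ex$n)
  os <- standardize_effects(ou$beta, ou$se, ou$n)
  keep <- rep(TRUE, length(common))
  if (!is.null(steiger_p))
    keep <- steiger_filter(es$beta, es$se, os$beta, os$se, steiger_p)
  if (sum(keep) < min_ivs)
    stop(structure(class = c("couplemr_screen_failure", "error", "condition"),
                   list(message = sprintf("only %d instruments survive (need >= %d)",
                                          sum(keep), min_ivs),
                        call = sys.call())))
  est <- ivw_estimate(es$beta[keep], os$beta[keep], os$se[keep])
  attr(est, "n_ivs") <- sum(keep)
  est
}

#' Single-trait cross-partner MR on a simulated cohort
#'
#' The full single-trait analysis for one trait: sex-specific exposure GWAS on
#' the index persons and outcome GWAS (partner phenotype on index genotype),
#' SNP-level fixed-effect pooling across sexes, genome-wide-significance
#' instrument selection with optional LD pruning, between-sex heterogeneity
#' filtering, effect standardization and IVW.
#'
#' @param cohort a `couple_cohort`.
#' @param trait trait name.
#' @param p_instrument instrument association threshold (default 5e-8).
#' @param r2_prune LD pruning threshold (used when `ld` given).
#' @param ld optional LD correlation matrix.
#' @param min_ivs minimum surviving instruments (default 5).
#' @param sex_het apply the between-sex heterogeneity filter (default TRUE).
#' @param outcome_person `"partner"` for the cross-partner design, `"index"`
#'   for a same-person (self) MR sanity check.
#' @param snps optional SNP subset (e.g. the trait's own loci in a network
#'   cohort).
#' @return an `mr_estimate` on the standardized scale.
#' @export
single_trait_couple_mr <- function(cohort, trait = "X", p_instrument = 5e-8,
                                   r2_prune = 0.001, ld = NULL, min_ivs = 5,
                                   sex_het = TRUE,
                                   outcome_person = "partner", snps = NULL) {
  if (is.null(snps) && !is.null(cohort$snps$trait)) snps <- trait_snps(cohort, trait)
  exp_m <- emulate_gwas_summary(cohort, trait, "index", sex = "M", snps = snps)
  exp_f <- emulate_gwas_summary(cohort, trait, "index", sex = "F", snps = snps)
  common <- intersect(exp_m$snp, exp_f$snp)
  exp_m <- exp_m[match(common, exp_m$snp), ]
  exp_f <- exp_f[match(common, exp_f$snp), ]
  pooled <- meta_fixed(exp_m$beta, exp_m$se, exp_f$beta, exp_f$se)
  exp_stats <- data.frame(snp = common, beta = pooled$beta, se = pooled$se,
                          n = exp_m$n + exp_f$n,
                          pval = 2 * stats::pnorm(-abs(pooled$beta / pooled$se)),
                          stringsAsFactors = FALSE)
  iv <- select_instruments(exp_stats, ld = ld, p_threshold = p_instrument,
                           r2_threshold = r2_prune)
  if (sex_het && nrow(iv) > 0) {
    im <- match(iv$snp, exp_m$snp)
    keep <- sex_heterogeneity_filter(exp_m$beta[im], exp_m$se[im],
                                     exp_f$beta[im], exp_f$se[im], nrow(iv))
    iv <- iv[keep, , drop = FALSE]
  }
  if (nrow(iv) < min_ivs)
    stop(structure(class = c("couplemr_screen_failure", "error", "condition"),
                   list(message = sprintf("trait %s: only %d valid instruments (need >= %d)",
                                          trait, nrow(iv), min_ivs),
                        call = sys.call())))
  out_stats <- emulate_gwas_sex_meta(cohort, trait, outcome_person, snps = iv$snp)
  couple_mr_from_stats(iv, out_stats, steiger_p = NULL, min_ivs = min_ivs)
}

#' Z test comparing the couple correlation with the MR estimate
#'
#' Two-sided normal test of `r - alpha` treating the two estimates as
#' independent: \eqn{z = (r - \alpha)/\sqrt{se_r^2 + se_\alpha^2}}.
#'
#' @param r,se_r couple Pearson correlation and its standard error.
#' @param alpha,se_alpha MR estimate and its standard error.
#' @return list with `z` and two-sided `pval`.
#' @export
compare_corr_vs_mr <- function(r, se_r, alpha, se_alpha) {
  if (any(c(se_r, se_alpha) <= 0)) stop_invalid("standard errors must be positive")
  z <- (r - alpha) / sqrt(se_r^2 + se_alpha^2)
  list(z = z, pval = 2 * stats::pnorm(-abs(z)))
}

#' Split couples into roughly equal-sized quantile bins
#'
#' Quantile-based edges with tie groups kept intact (all couples sharing a
#' value land in the same bin), so bin sizes can differ when the binning value
#' is heavily tied.
#'
#' @param values couple-level binning variable (e.g. time at current address).
#' @param n_bins number of bins (default 5).
#' @return list with `bin` (integer assignment, 1..B), `medians` (per-bin
#'   median of `values`, the bin centre) and `sizes`.
#' @export
bin_couples <- function(values, n_bins = 5) {
  if (length(unique(values)) < n_bins)
    stop_invalid("fewer distinct values than bins")
  # integer-arithmetic quantile edges (floating-point probs can shift a cut
  # point by one observation)
  sx <- sort(values)
  n <- length(sx)
  cuts <- sx[vapply(seq_len(n_bins - 1),
                    function(k) (n * k) %/% n_bins + ((n * k) %% n_bins > 0),
                    numeric(1))]
  edges <- unique(c(sx[1], cuts, sx[n]))
  bin <- cut(values, breaks = edges, include.lowest = TRUE, labels = FALSE)
  bin <- match(bin, sort(unique(bin)))  # compact labels if edges collapsed
  meds <- as.numeric(tapply(values, bin, stats::median))
  list(bin = bin, medians = meds, sizes = as.integer(table(bin)))
}

#' Weighted trend test across bins
#'
#' Weighted least-squares regression of per-bin estimates on the bin centres
#' with weights `1/se` (inverse standard error, the convention used for the
#' convergence analyses), returning the slope, its standard error and a
#' two-sided p-value.
#'
#' @param estimates per-bin estimates (correlations or MR effects).
#' @param se their standard errors.
#' @param centres bin centres (per-bin median of the binning variable).
#' @return list with `slope`, `se`, `pval`, plus the per-bin inputs.
#' @export
trend_test <- function(estimates, se, centres) {
  if (length(estimates) < 3) stop_invalid("need at least 3 bins")
  if (any(se <= 0)) stop_invalid("standard errors must be positive")
  if (stats::sd(centres) == 0) stop_invalid("degenerate design: constant bin centres")
  fit <- stats::lm(estimates ~ centres, weights = 1 / se)
  sm <- summary(fit)$coefficients
  list(slope = sm["centres", "Estimate"], se = sm["centres", "Std. Error"],
       pval = sm["centres", "Pr(>|t|)"],
       estimates = estimates, bin_se = se, centres = centres)
}
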