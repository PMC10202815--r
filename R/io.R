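#' Read GWAS summary statistics from a tab-separated file
#'
#' Requires a header with columns `snp`, `effect_allele`, `beta`, `se`, `n`,
#' `pval` (an `other_allele` column is kept when present). Rows failing basic
#' validity (non-positive se, n < 1, p outside `[0, 1]`) are rejected with
#' their line numbers.
#'
#' @param path file path.
#' @return summary-statistics data.frame.
#' @export
read_summary_stats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("snp", "effect_allele", "beta", "se", "n", "pval")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop_invalid("summary-statistics file is missing column(s): ",
                 paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(df$se) | df$se <= 0 | df$n < 1 |
                 !is.finite(df$pval) | df$pval < 0 | df$pval > 1)
  if (length(bad))
    stop_invalid("malformed summary-statistics rows (file lines): ",
                 paste(bad + 1L, collapse = ", "))
  df
}

#' Write summary statistics (tab-separated, full precision)
#' @param stats summary-statistics data.frame.
#' @param path output path.
#' @export
write_summary_stats <- function(stats, path) {
  write_tsv(stats, path)
}

# canonical tabular writer: tab-separated, header, full precision, empty
# fields for missing values
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 17, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Matches by SNP id; where the effect alleles disagree the outcome beta sign
#' is flipped (allele-swap harmonization). Strand-ambiguous palindromic SNPs
#' (A/T or C/G allele pairs, detectable when `other_allele` is present) are
#' dropped with a warning.
#'
#' @param exposure,outcome summary-statistics data.frames.
#' @return list with aligned `exposure` and `outcome` tables (same SNP order).
#' @export
harmonize_stats <- function(exposure, outcome) {
  common <- intersect(exposure$snp, outcome$snp)
  ex <- exposure[match(common, exposure$snp), , drop = FALSE]
  ou <- outcome[match(common, outcome$snp), , drop = FALSE]
  if (!is.null(ex$other_allele)) {
    comp <- chartr("ACGT", "TGCA", ex$effect_allele)
    pal <- comp == ex$other_allele
    if (any(pal)) {
      warning(sum(pal), " strand-ambiguous palindromic SNP(s) dropped")
      ex <- ex[!pal, , drop = FALSE]; ou <- ou[!pal, , drop = FALSE]
    }
  }
  flip <- ex$effect_allele != ou$effect_allele
  ou$beta[flip] <- -ou$beta[flip]
  ou$effect_allele[flip] <- ex$effect_allele[flip]
  list(exposure = ex, outcome = ou)
}

#' Read a square LD correlation matrix
#'
#' Tab-separated with SNP ids as both the header row and the first column.
#'
#' @param path file path.
#' @return numeric matrix with SNP-id dimnames.
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop_invalid("LD matrix must be square with matching row/column SNP ids")
  m
}

#' Write the phenotype and genotype tables of a cohort
#'
#' Phenotype table: one row per person (`household_id`, `person_role`, `sex`,
#' `age`, `time_at_address`, one column per trait). Genotype table: one row per
#' person (`person_id` then one column per SNP id, dosages 0/1/2).
#'
#' @param cohort a `couple_cohort`.
#' @param pheno_path,geno_path output paths.
#' @return invisibly, the phenotype data.frame.
#' @export
write_cohort <- function(cohort, pheno_path, geno_path = NULL) {
  traits <- intersect(c("X", "Y"), names(cohort$index))
  one_side <- function(side, role) {
    df <- data.frame(household_id = cohort$couples$household_id,
                     person_role = role, sex = side$sex, age = side$age,
                     time_at_address = side$time_at_address)
    for (tr in traits) df[[tr]] <- side[[tr]]
    df
  }
  ph <- rbind(one_side(cohort$index, "index"), one_side(cohort$partner, "partner"))
  ph <- ph[order(ph$household_id, ph$person_role), ]
  write_tsv(ph, pheno_path)
  if (!is.null(geno_path)) {
    g <- as.data.frame(cohort$index$geno)
    g <- cbind(person_id = paste0("index_", cohort$couples$household_id), g)
    write_tsv(g, geno_path)
  }
  invisible(ph)
}

#' Read a run configuration from YAML
#'
#' Fills unspecified thresholds with the pipeline defaults and validates
#' ranges.
#'
#' @param path YAML file path.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(n_couples = 20000L, n_snps = 100L, maf = 0.5, h2 = 0.2,
                   r_x = 0.2, r_e = 0, r_g = 0, s_g = 0, s_e = 0, s_x = 0,
                   p_instrument = 5e-8, r2_prune = 0.001, steiger_p = 0.001,
                   corr_threshold = 0.1, min_ivs = 5L,
                   confounder_corr_cap = 0.8, confounder_prune_r2 = 0.1,
                   n_bins = 5L, seed = 1L)
  cfg <- utils::modifyList(defaults, cfg)
  with(cfg, {
    stopifnot(p_instrument > 0, p_instrument < 1, r2_prune >= 0, r2_prune <= 1,
              steiger_p > 0, steiger_p < 1, min_ivs >= 1, n_bins >= 2,
              confounder_corr_cap > 0, confounder_corr_cap <= 1)
  })
  cfg
}
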