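#' Run the full cross-partner MR pipeline on a simulated cohort
#'
#' Chains all stages end-to-end on synthetic data: cohort simulation, trait
#' screening, single-trait couple MR with the correlation-versus-MR contrast,
#' time/age-bin trend analysis, the confounding decomposition on a two-trait
#' network, the cross-trait couple MR with path decomposition, and the analytic
#' bias grid. Every stage writes a tab-separated table under `out_dir` and is
#' listed in `manifest.json` together with the configuration hash and seed, so
#' identical config + seed reproduce identical outputs.
#'
#' @param config named list as returned by [read_run_config()] (or a YAML path).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   seed = config$seed,
                   r_version = as.character(getRversion()),
                   stages = character(0))
  note <- function(stage, file) manifest$stages <<- c(manifest$stages,
                                                      stats::setNames(file, stage))
  fail <- function(stage, e) {
    writeLines(paste0("FAILED at stage '", stage, "': ", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }

  res <- list()
  with_seed(config$seed, {
    ## stage 1: simulate
    stage <- "simulate"
    tryCatch({
      params <- couple_model_params(
        n_couples = config$n_couples, n_snps = config$n_snps, maf = config$maf,
        h2 = config$h2, r_g = config$r_g, r_e = config$r_e, r_x = config$r_x,
        s_g = config$s_g, s_e = config$s_e, s_x = config$s_x)
      res$cohort <- simulate_couple_cohort(params)
      write_cohort(res$cohort, file.path(out_dir, "phenotypes.tsv"))
      note(stage, "phenotypes.tsv")
    }, error = function(e) fail(stage, e))

    ## stage 2: screen
    stage <- "screen"
    tryCatch({
      ct <- couple_table(res$cohort)
      cc <- couple_correlation(ct$x_i, ct$x_p)
      exp_stats <- emulate_gwas_sex_meta(res$cohort, "X", "index")
      iv <- select_instruments(exp_stats, p_threshold = config$p_instrument)
      res$screen <- screen_traits(
        data.frame(trait = "X", r = cc$r, n_valid_ivs = nrow(iv)),
        corr_threshold = config$corr_threshold, min_ivs = config$min_ivs)
      res$screen$r_se <- cc$se; res$screen$spearman <- cc$spearman
      res$screen$n_pairs <- cc$n
      write_tsv(res$screen, file.path(out_dir, "screen.tsv"))
      note(stage, "screen.tsv")
    }, error = function(e) fail(stage, e))

    ## stage 3: single-trait couple MR + correlation-vs-MR contrast
    stage <- "couple_mr"
    tryCatch({
      tab <- res$screen
      if (any(tab$retained)) {
        mr <- single_trait_couple_mr(res$cohort, "X",
                                     p_instrument = config$p_instrument,
                                     min_ivs = config$min_ivs)
        cmp <- compare_corr_vs_mr(tab$r, tab$r_se, mr$alpha, mr$se)
        res$couple_mr <- data.frame(trait = "X", pheno_couple_r = tab$r,
                                    pheno_couple_r_se = tab$r_se,
                                    IVW_beta = mr$alpha, IVW_se = mr$se,
                                    IVW_pval = mr$pval, n_ivs = mr$k,
                                    Q = mr$q, Q_pval = mr$q_pval,
                                    couple_r_versus_IVW_diff_pval = cmp$pval)
      } else {
        res$couple_mr <- data.frame()
      }
      write_tsv(res$couple_mr, file.path(out_dir, "couple_mr.tsv"))
      note(stage, "couple_mr.tsv")
    }, error = function(e) fail(stage, e))

    ## stage 4: trend over time-together bins
    stage <- "trend"
    tryCatch({
      res$trend <- if (nrow(res$couple_mr)) {
        tr <- cohort_trend(res$cohort, n_bins = config$n_bins)
        data.frame(binning = "time_together", slope = tr$slope,
                   slope_se = tr$se, slope_pval = tr$pval)
      } else data.frame()
      write_tsv(res$trend, file.path(out_dir, "trend.tsv"))
      note(stage, "trend.tsv")
    }, error = function(e) fail(stage, e))

    ## stage 5: confounding decomposition on a two-trait network cohort
    stage <- "confounding"
    tryCatch({
      np <- trait_network_params(n_couples = config$n_couples,
                                 n_snps_x = config$n_snps, n_snps_y = config$n_snps,
                                 alpha_y_to_x = 0.5, r_y = 0.4, r_x = 0)
      res$confounding <- tryCatch(
        confounding_analysis(simulate_trait_network(np),
                             min_ivs = config$min_ivs,
                             p_instrument = config$p_instrument),
        couplemr_screen_failure = function(e) data.frame())
      write_tsv(res$confounding, file.path(out_dir, "confounding.tsv"))
      note(stage, "confounding.tsv")
    }, error = function(e) fail(stage, e))

    ## stage 6: cross-trait MR + path decomposition
    stage <- "paths"
    tryCatch({
      np <- trait_network_params(n_couples = config$n_couples,
                                 n_snps_x = config$n_snps, n_snps_y = config$n_snps,
                                 alpha_x_to_y = 0.3, r_x = config$r_x)
      res$paths <- tryCatch(
        path_analysis(simulate_trait_network(np),
                      min_ivs = config$min_ivs,
                      p_instrument = config$p_instrument,
                      steiger_p = config$steiger_p),
        couplemr_screen_failure = function(e) data.frame())
      write_tsv(res$paths, file.path(out_dir, "paths.tsv"))
      note(stage, "paths.tsv")
    }, error = function(e) fail(stage, e))

    ## stage 7: analytic bias grid
    stage <- "bias_grid"
    tryCatch({
      res$bias_grid <- bias_grid(bias_params(h2 = config$h2, r_x = config$r_x),
                                 vary = c("r_e", "s_x"),
                                 ranges = list(c(-0.3, 0.3), c(-0.3, 0.3)))
      write_tsv(res$bias_grid, file.path(out_dir, "bias_grid.tsv"))
      note(stage, "bias_grid.tsv")
    }, error = function(e) fail(stage, e))

    ## stage 8: manifest
    stage <- "manifest"
    tryCatch({
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      note(stage, "manifest.json")
    }, error = function(e) fail(stage, e))
  })
  res$manifest <- manifest
  invisible(res)
}

#' Trend of the couple correlation across time-together bins
#'
#' Bins couples on the shared time-together proxy, computes the per-bin couple
#' correlation of the focal trait and runs the inverse-SE-weighted trend test
#' against the bin centres.
#'
#' @param cohort a `couple_cohort`.
#' @param trait trait name.
#' @param n_bins number of quantile bins (default 5).
#' @param statistic `"correlation"` (per-bin couple Pearson r) or `"mr"`
#'   (per-bin cross-partner IVW estimate; outcome effects re-estimated per bin,
#'   exposure effects from the full sample).
#' @return a [trend_test()] result.
#' @export
cohort_trend <- function(cohort, trait = "X", n_bins = 5,
                         statistic = c("correlation", "mr")) {
  statistic <- match.arg(statistic)
  ct <- couple_table(cohort, trait)
  bins <- bin_couples(ct$time_together, n_bins = n_bins)
  est <- se <- numeric(length(bins$medians))
  if (statistic == "correlation") {
    for (b in seq_along(bins$medians)) {
      idx <- bins$bin == b
      cc <- couple_correlation(ct$x_i[idx], ct$x_p[idx])
      est[b] <- cc$r; se[b] <- cc$se
    }
  } else {
    snps <- if (!is.null(cohort$snps$trait)) trait_snps(cohort, trait) else NULL
    exp_stats <- emulate_gwas_sex_meta(cohort, trait, "index", snps = snps)
    for (b in seq_along(bins$medians)) {
      sub <- subset_couples(cohort, bins$bin == b)
      out_stats <- emulate_gwas_sex_meta(sub, trait, "partner", snps = snps)
      mr <- couple_mr_from_stats(exp_stats, out_stats)
      est[b] <- mr$alpha; se[b] <- mr$se
    }
  }
  trend_test(est, se, bins$medians)
}

#' Subset a cohort to a set of couples
#' @param cohort a `couple_cohort`.
#' @param keep logical or integer index over couples.
#' @return the subsetted `couple_cohort`.
#' @export
subset_couples <- function(cohort, keep) {
  for (side in c("index", "partner"))
    cohort[[side]] <- lapply(cohort[[side]], function(v)
      if (is.matrix(v)) v[keep, , drop = FALSE] else v[keep])
  cohort$couples <- cohort$couples[keep, , drop = FALSE]
  cohort
}

#' Confounding decomposition on a two-trait network cohort
#'
#' For a cohort where trait Y confounds the couple correlation of trait X
#' (Y causes X within person; couples assort on Y), estimates the same-person
#' MR effect of Y on X, the within-couple MR effect of Y, the induced
#' confounding correlation C with its variance, the raw couple correlation of
#' X, the cross-partner MR estimate for X, and the confounding ratio.
#'
#' @param cohort a two-trait `couple_cohort` (confounder direction:
#'   `alpha_y_to_x` nonzero).
#' @param min_ivs,p_instrument instrument screen settings.
#' @return one-row data.frame with the estimates and standard errors.
#' @export
confounding_analysis <- function(cohort, min_ivs = 5, p_instrument = 5e-8) {
  # same-person MR: Y (exposure, index persons) -> X (same person)
  exp_y <- emulate_gwas_sex_meta(cohort, "Y", "index", snps = trait_snps(cohort, "Y"))
  iv_y <- select_instruments(exp_y, p_threshold = p_instrument)
  out_x_same <- emulate_gwas_sex_meta(cohort, "X", "index", snps = iv_y$snp)
  mr_yx <- couple_mr_from_stats(iv_y, out_x_same, steiger_p = 0.001, min_ivs = min_ivs)
  # within-couple MR: Y_i -> Y_p
  mr_yy <- single_trait_couple_mr(cohort, "Y", p_instrument = p_instrument,
                                  min_ivs = min_ivs)
  # cross-partner MR for the focal trait X and its raw couple correlation
  mr_xx <- single_trait_couple_mr(cohort, "X", p_instrument = p_instrument,
                                  min_ivs = min_ivs)
  ct <- couple_table(cohort, "X")
  cc <- couple_correlation(ct$x_i, ct$x_p)
  C <- confounding_correlation(mr_yx$alpha, mr_yy$alpha)
  var_C <- confounding_variance(mr_yx$alpha, mr_yx$se, mr_yy$alpha, mr_yy$se)
  data.frame(alpha_y_to_x = mr_yx$alpha, se_y_to_x = mr_yx$se,
             alpha_yi_to_yp = mr_yy$alpha, se_yi_to_yp = mr_yy$se,
             C = C, se_C = sqrt(var_C),
             couple_r = cc$r, couple_r_se = cc$se,
             IVW_beta_x = mr_xx$alpha, IVW_se_x = mr_xx$se,
             confounding_ratio = confounding_ratio(C, cc$r))
}

#' Cross-trait path decomposition on a two-trait network cohort
#'
#' Estimates omega (cross-trait couple MR X_i -> Y_p), gamma (single-trait
#' couple MR on X times the same-person X -> Y effect) and rho (MVMR
#' `Y_p ~ Y_i + X_i` coefficient of Y_i times the same-person effect) on one
#' simulated trait pair.
#'
#' @param cohort a two-trait `couple_cohort` (causal direction `alpha_x_to_y`).
#' @param min_ivs,p_instrument,steiger_p analysis settings.
#' @return one-row data.frame with omega/gamma/rho and standard errors.
#' @export
path_analysis <- function(cohort, min_ivs = 5, p_instrument = 5e-8,
                          steiger_p = 0.001) {
  snps_x <- trait_snps(cohort, "X"); snps_y <- trait_snps(cohort, "Y")
  # omega: X_i -> Y_p
  exp_x <- emulate_gwas_sex_meta(cohort, "X", "index", snps = snps_x)
  iv_x <- select_instruments(exp_x, p_threshold = p_instrument)
  out_y_p <- emulate_gwas_sex_meta(cohort, "Y", "partner", snps = iv_x$snp)
  ct_xy <- stats::cor(cohort$index$X, cohort$index$Y)
  omega <- estimate_omega(iv_x, out_y_p, pair_corr = ct_xy,
                          steiger_p = steiger_p, min_ivs = min_ivs)
  # same-person X -> Y
  out_y_same <- emulate_gwas_sex_meta(cohort, "Y", "index", snps = iv_x$snp)
  mr_xy <- couple_mr_from_stats(iv_x, out_y_same, steiger_p = steiger_p,
                                min_ivs = min_ivs)
  # gamma: couple effect on X times alpha_x_to_y
  mr_xx <- single_trait_couple_mr(cohort, "X", p_instrument = p_instrument,
                                  min_ivs = min_ivs)
  gam <- estimate_gamma(mr_xx$alpha, mr_xx$se, mr_xy$alpha, mr_xy$se)
  # rho: MVMR Y_p ~ Y_i + X_i on pooled standardized instruments
  pooled <- rbind(select_instruments(exp_x, p_threshold = p_instrument),
                  select_instruments(
                    emulate_gwas_sex_meta(cohort, "Y", "index", snps = snps_y),
                    p_threshold = p_instrument))
  y_i <- emulate_gwas_sex_meta(cohort, "Y", "index", snps = pooled$snp)
  x_i <- emulate_gwas_sex_meta(cohort, "X", "index", snps = pooled$snp)
  y_p <- emulate_gwas_sex_meta(cohort, "Y", "partner", snps = pooled$snp)
  sy_i <- standardize_effects(y_i$beta, y_i$se, y_i$n)
  sx_i <- standardize_effects(x_i$beta, x_i$se, x_i$n)
  sy_p <- standardize_effects(y_p$beta, y_p$se, y_p$n)
  mv <- mvmr_estimate(sy_p$beta, sy_p$se,
                      cbind(Y_i = sy_i$beta, X_i = sx_i$beta))
  rho <- estimate_rho(mv, mr_xy$alpha, mr_xy$se)
  data.frame(omega = omega$alpha, se_omega = omega$se,
             gamma = gam$gamma, se_gamma = gam$se,
             rho = rho$rho, se_rho = rho$se,
             alpha_x_to_y = mr_xy$alpha, se_x_to_y = mr_xy$se,
             alpha_xi_xp = mr_xx$alpha, se_xi_xp = mr_xx$se,
             alpha_yi_yp_mvmr = rho$alpha_yi_yp, se_yi_yp_mvmr = rho$se_yi_yp)
}
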