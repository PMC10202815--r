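#!/usr/bin/env Rscript

# Cross-trait path decomposition: the total cross-partner effect omega of
# trait X in the index on trait Y in the partner is dissected into the
# exposure-assortment path gamma (X_i -> X_p -> Y_p) and the
# outcome-assortment path rho (X_i -> Y_i -> Y_p), plus a direct-effect
# residual. Three generative designs make each mechanism dominant in turn;
# an ensemble of replicates then exercises the across-pair contrasts
# (paired t test, through-origin regression, R^2).

suppressMessages(library(couplemr))
dir.create("results", showWarnings = FALSE)

designs <- list(
  exposure_assortment = trait_network_params(5e4, alpha_x_to_y = 0.3,
                                             r_x = 0.2, seed = 41),
  outcome_assortment = trait_network_params(5e4, alpha_x_to_y = 0.3,
                                            r_y = 0.2, seed = 42),
  direct_effect = trait_network_params(5e4, alpha_x_to_y = 0.3, r_x = 0.2,
                                       direct_xi_to_yp = 0.1, seed = 43))

rows <- do.call(rbind, lapply(names(designs), function(nm) {
  pa <- path_analysis(simulate_trait_network(designs[[nm]]))
  cbind(design = nm, pa)
}))
write.table(format(rows, digits = 4), "results/path_designs.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Path decomposition by design (truth: omega = 0.06 for assortment designs):\n")
print(rows[, c("design", "omega", "se_omega", "gamma", "se_gamma",
               "rho", "se_rho")], digits = 3, row.names = FALSE)
cat("\n  exposure design: omega is carried by gamma; rho ~ 0\n")
cat("  outcome design:  omega is carried by rho; gamma ~ r_y*alpha^3 = 0.0054\n")
cat(sprintf("  direct design:   omega (%.3f) exceeds gamma + rho (%.3f) by ~0.1, the injected direct effect\n\n",
            rows$omega[3], rows$gamma[3] + rows$rho[3]))

# ensemble of gamma-dominated trait pairs for the across-pair contrasts
set.seed(44)
ens <- do.call(rbind, lapply(1:8, function(i) {
  np <- trait_network_params(2e4, alpha_x_to_y = runif(1, 0.2, 0.4),
                             r_x = runif(1, 0.1, 0.25), seed = 100 + i)
  pa <- path_analysis(simulate_trait_network(np))
  cbind(pair = paste0("pair", i), pa)
}))
cmp <- compare_paths(data.frame(pair = ens$pair, omega = ens$omega,
                                se_omega = ens$se_omega, gamma = ens$gamma,
                                se_gamma = ens$se_gamma, rho = ens$rho,
                                se_rho = ens$se_rho))
write.table(format(cmp$paths, digits = 4), "results/path_ensemble.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Ensemble of 8 exposure-assortment pairs:\n")
cat(sprintf("  pairs with |gamma| > |rho|: %d of %d\n",
            sum(cmp$paths$category == "gamma_dominated"), nrow(cmp$paths)))
if (!is.null(cmp$paired_t))
  cat(sprintf("  paired t (|gamma| vs |rho|): t = %.2f, p = %.2g (%d sign-mismatched pairs removed)\n",
              cmp$paired_t$statistic, cmp$paired_t$p.value, cmp$n_sign_mismatch))
cat(sprintf("  through-origin regression of omega on gamma + rho_resid: slope %.3f (se %.3f), R^2 = %.3f\n",
            cmp$origin_slope, cmp$origin_slope_se, cmp$r2_origin))
cat(sprintf("  cor(rho, gamma) across pairs: %.3f\n", cmp$rho_gamma_cor))
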