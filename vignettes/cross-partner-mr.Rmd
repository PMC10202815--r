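---
title: "Cross-partner Mendelian randomization: model, estimators and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-partner Mendelian randomization: model, estimators and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Partners resemble each other in many phenotypes. Three mechanisms can produce
such similarity: assortative mating (partner choice on the trait itself),
confounding (choice on a correlated trait that causally feeds the focal
trait), and convergence (mutual influence after couple formation).
`couplemr` implements a framework that separates these mechanisms by
extending Mendelian randomization (MR) across partners: the exposure is a
trait of an index individual, instrumented by that individual's genetic
variants, and the outcome is a trait of their partner. Because the index
genotype is fixed at conception, a nonzero cross-partner estimate reflects
processes downstream of the index trait — partner choice on it or influence
through it — rather than shared environment after pairing.

Everything here runs on synthetic cohorts; the package is a tested
implementation of the full analysis chain, exercisable end to end without any
restricted biobank data.

# The structural couple model

Each person's trait is

$$X = g\,G + e\,E, \qquad g^2 + e^2 = 1,$$

with a standardized polygenic score $G$ (equal per-SNP contributions from
`n_snps` unlinked biallelic loci, Hardy–Weinberg genotypes, Mendelian
transmission from simulated parents) and a standard-normal environment $E$.
The defaults fix the heritability at 20% ($g = \sqrt{0.2}$), the value used
throughout the reference analyses.

The offspring environment receives parental contributions

$$E_O = s_G\,G_P + s_E\,E_P + s_X\,X_P + \text{residual},$$

where each parental aggregate is the rescaled mean of the two parents,
$X_P = (X_M + X_F)/\sqrt{2(1 + \mathrm{cor}(X_M, X_F))}$, which keeps every
parental variable at unit variance. The residual is rescaled so that
$\mathrm{Var}(E_O) = 1$, keeping $g$ and $e$ interpretable as path
coefficients on unit-variance components. Mendelian transmission makes
$\mathrm{cor}(G_P, G_O) = 1/\sqrt{2}$ by construction — a built-in identity
the tests verify across parameter settings. Exactly one parental generation is
simulated, itself assorted with the same coefficients as the offspring
generation but with no grandparental effects; an equilibrium (iterated)
assortment model would strengthen the parental-couple correlations slightly,
which is a known simplification.

Couples form under simultaneous direct assortment on the genetic score, the
environment and the trait, with coefficients $r_G$, $r_E$, $r_X$. The model's
closed-form expectations are additive in these sources, e.g.

$$\mathrm{cor}(X_i, X_p) = r_X + r_E\,e^2 + r_G\,g^2,$$

and the genotype–environment correlation induced by parental effects is
$t = (s_G + g\,s_X)/\sqrt{2}$.

## How couples are paired

The model states target correlations, not a pairing algorithm. For a single
assortment variable the package uses Gaussian-copula rank matching
(`assort_pairs`): draw a latent bivariate normal at the target correlation,
and pair candidates by latent ranks. This achieves arbitrary targets without
touching the marginal distributions.

For simultaneous assortment on $(G, E, X)$ a single matching variable cannot
work: matching on one composite induces a rank-one cross-partner covariance,
while the additive model above is a sum of three rank-one terms. At, say,
$r_X = 0.2$ and $r_E = 0.3$ a composite fit that reproduces the three
same-variable correlations distorts $\mathrm{cov}(G_i, X_p)$ — the quantity
the MR estimator lives on — by about 14% relative, visibly breaking the
agreement between simulated and analytic estimates. `couplemr` therefore
pairs couples through a *mixture of single-variable assortment channels*:
each couple is assigned to one channel $j \in \{G, E, X\}$ with probability
$|r_j| / \sum_k |r_k|$ and rank-matched on that variable alone at correlation
$\mathrm{sign}(r_j) \sum_k |r_k|$. The population cross-covariance is then
exactly

$$\sum_j r_j\, \frac{\sigma_j \sigma_j^\top}{\mathrm{Var}(V_j)},
\qquad \sigma_j = \mathrm{cov}(v, V_j),$$

the additive decomposition the model assumes. The mixture is not jointly
Gaussian, but every quantity the analyses use (correlations, per-SNP
regressions, IVW) depends only on second moments, which the mixture matches.
Feasibility requires $\sum_j |r_j| \le 1$; infeasible targets raise an
explicit error.

The closed-form correlation expectations are first-order path-tracing
approximations: they drop terms of order $r \cdot t^2$ and the inflation of
$\mathrm{Var}(X)$ above 1 when parental effects are active
($\mathrm{Var}(X) = 1 + 2ge\,t$). At the parameter magnitudes explored here
(|r| ≤ 0.3, |s| ≤ 0.3) these corrections are below ~0.01 and the agreement is
verified by simulation rather than assumed.

# Estimators

* **IVW** (`ivw_estimate`): $\hat\alpha = \sum_k \beta_k^X \beta_k^Y
  (\sigma_k^Y)^{-2} \big/ \sum_k (\beta_k^X)^2 (\sigma_k^Y)^{-2}$ with
  $\mathrm{Var}(\hat\alpha)$ the reciprocal of the denominator — exactly the
  no-intercept weighted least-squares slope, and the Wald ratio for one
  instrument. Cochran's $Q$ uses delta-method Wald-ratio precisions
  $(\beta_k^X)^2/(\sigma_k^Y)^2$, consistent with the IVW weights.
* **Standardization** (`standardize_effects`): summary effects are converted
  to the correlation scale with $b = z/\sqrt{n - 2 + z^2}$, exact for a
  univariate regression on standardized variables and computable from
  $(\beta, se, n)$ alone. Squared standardized effects are variances
  explained, making couple correlations and MR estimates directly comparable.
* **Steiger directionality filter** (`steiger_filter`): an instrument is
  dropped iff its absolute standardized outcome effect exceeds the exposure
  effect *and* the one-tailed normal test of the difference (variance
  $se_x^2 + se_y^2$, treating the two datasets as independent) is significant
  at 0.001. The exact test-statistic convention is a documented choice; the
  filter's limiting behaviour (threshold $\to$ 0 retains everything,
  threshold 1 removes every reverse-oriented SNP) is property-tested.
* **Sex handling**: all SNP effects are estimated in male-index and
  female-index couples separately and pooled per SNP by fixed-effect
  meta-analysis *before* MR (pooling estimates rather than MR results avoids
  compounding weak-instrument bias); instruments with Bonferroni-significant
  between-sex heterogeneity ($p < 0.05/\#\text{IV}$) are excluded.
* **Instrument selection** (`select_instruments`): genome-wide significance
  ($p < 5\times10^{-8}$) plus greedy $r^2 < 0.001$ pruning over a provided LD
  matrix, ordered by ascending p-value. Physical-distance clumping is
  abstracted away: with an LD matrix covering the locus the two are
  equivalent, and simulated loci are unlinked unless the AR(1) LD option is
  enabled.
* **MVMR** (`mvmr_estimate`): weighted no-intercept multiple regression of
  outcome effects on several exposures' effects. Exposure columns that are
  identically zero are dropped (their direct effect is unidentified) with an
  `NA` coefficient, so the remaining fit is the nested model; genuinely
  collinear exposures raise an error, mirroring the numerical instability
  that motivates univariable-plus-pruning for confounder sets.
* **Effective number of tests** (`effective_tests`): the Li–Ji eigenvalue
  estimator on the absolute trait correlation matrix; eigenvalues are clipped
  at zero (with a warning) for indefinite inputs and rounded to 8 decimals so
  an eigenvalue of exactly $k$ is not floored to $k-1$ by floating-point
  error.

# The analysis chain

1. **Couple identification** (`identify_couples`): households with exactly two
   unrelated, opposite-sex members, both self-reporting as partners; per-rule
   exclusion counts are returned.
2. **Phenotype processing**: rank-preserving inverse normal transformation
   (Blom offset 3/8, average ranks for ties); traits screened on couple
   Pearson correlation $> 0.1$ and $\ge 5$ valid instruments.
3. **Single-trait couple MR** (`single_trait_couple_mr`) and the two-sided Z
   contrast of $\hat r$ versus $\hat\alpha$
   (`compare_corr_vs_mr`), with multiple testing governed by the effective
   number of tests.
4. **Convergence** (`bin_couples`, `trend_test`, `cohort_trend`): couples are
   split into five quantile bins of time-at-address (tie groups kept intact;
   integer-arithmetic quantile edges so a cut point cannot shift by one
   observation through floating-point probabilities), and the per-bin
   estimates are regressed on bin medians weighted by $1/se$ — inverse
   standard error, not inverse variance, following the stated convention.
5. **Confounding** (`confounder_scan`, `confounding_correlation`,
   `prune_confounders`, `confounding_ratio`): a confounder $Y$ induces
   $C = \alpha_{y \to x}^2\, \alpha_{y_i \to y_p}$ of couple correlation;
   $\mathrm{Var}(C)$ combines $\mathrm{Var}(X^2) = 4\mu^2\sigma^2 + 2\sigma^4$
   with the independent-product variance formula. Candidates pass three
   sequential filters (same-person effect at $0.05/M_{eff}$, within-couple
   effect at $0.05/\#\text{remaining}$, $|\mathrm{cor}(Y, X)| < 0.8$ computed
   on the pooled sample), are pruned greedily by descending $|C|$ at
   $r^2 < 0.1$ (ties by trait id), and the retained $C$ values sum with
   summed variances.
6. **Path decomposition** (`estimate_omega`, `estimate_gamma`,
   `estimate_rho`, `residualize_rho`, `compare_paths`): the total cross-trait
   effect $\omega$ is contrasted with $\gamma = \hat\alpha_{x_i \to x_p}
   \hat\alpha_{x \to y}$ and $\rho = \hat\alpha_{y_i \to y_p | X_i}
   \hat\alpha_{x \to y}$ (the $Y_i$ coefficient from the MVMR
   $Y_p \sim Y_i + X_i$). $\rho$ is residualized on $\gamma$ by OLS *with*
   intercept (the standard regression default) before the joint
   through-origin regression of $\omega$; the through-origin $R^2$ is
   uncentered ($1 - RSS/\sum \omega^2$), and that regression is unweighted.
   Pairs whose $\gamma$ and $\rho$ signs disagree are excluded from the
   paired t test of magnitudes.

# The analytic bias model

Under the structural model, the expected effect of the index genotype on the
index trait is $g + t\,e$ and on the partner's trait
$(g + t e)\,r_X + r_G\,g + t\,(r_E\,e)$, giving

$$E[\hat\alpha] \approx r_X +
  \frac{r_G\,g + t\,(r_E\,e)}{g + t\,e}, \qquad t = \tfrac{1}{\sqrt2}(s_G + g\,s_X).$$

Three facts follow and are verified both analytically and by simulation:
absent violations the estimator is unbiased for $r_X$; parental-environment
transmission $s_E$ never enters (no path from offspring genotype through the
parental environment); and genotype assortment at its *derived* magnitude
$r_G = (g\,r_G(X,Y))^2 r_Y$ produces bias an order of magnitude below
environmental assortment over the same secondary-trait range, because $r_G$
enters quadratically in $g\,r_G(X,Y)$. `bias_grid` evaluates the expectation
over 41×41 grids; `derived_violation_params` maps secondary-trait parameters
($r_G(X,Y) = 0.3$, $r_Y, s_Y \in [-0.3, 0.3]$) to induced violations.

The displayed expectation is a ratio of expectations, not the expectation of
the ratio; the package treats the formula as the definition and quantifies
the gap empirically, requiring agreement with full simulations within
$\max(0.02,\ 2\,\widehat{se}_{MC})$ over the explored grid.

# What the simulations do and do not establish

The generator reproduces the statistical skeleton the analyses assume:
polygenic architecture with equal per-SNP effects, Gaussian environments,
additive assortment channels, one assorted parental generation, linear
within-person trait networks, and missingness-free phenotypes. Real data
differ in ways the suite deliberately does not emulate: LD beyond the AR(1)
option, non-Gaussian and discretized phenotypes (ordinal/binary traits enter
the real pipeline as-is), measurement error (which attenuates estimates by
$\mathrm{Var}(y)/(\mathrm{Var}(y) + s^2)$; available as a qualitative
consideration, not a default), population structure, and genuine phenotype
curation. Passing tests therefore certify the estimators and the pipeline
logic, not robustness to those real-data features.

Two further caveats are quantified rather than hidden:

* **Dependence in the $\hat r$ vs $\hat\alpha$ contrast.** When both are
  estimated on the same couples they share sampling noise (correlation
  $\approx \sqrt{S}$ with $S$ the instrumented variance share), so the
  independence-assuming Z test is conservative — empirically ~2% rejection at
  nominal 5% under the null. The calibration suite therefore estimates the
  two quantities on disjoint couple halves, where the test is exactly
  calibrated, and separately asserts the overlapping version never exceeds
  the nominal level.
* **Weak-instrument attenuation.** With 100 SNPs carrying 20% heritability at
  $n = 5\times10^4$, the per-SNP noise inflates the IVW denominator by ~1%,
  an attenuation well inside Monte-Carlo error at these sizes but visible in
  principle.

# Problem sizes and reproducibility

The reference conditions are 50,000 couples and 100 SNPs; the package runs a
full single-trait analysis on them in a few seconds. The test suite uses
these sizes for the headline recovery checks, 4 replicates per point for the
3×3 analytic/stochastic grid, 30,000-couple cohorts for the network recovery
tests, and 500 replicates of 6,000-couple cohorts with 10 SNPs for the null
calibration — sizes chosen so each check's Monte-Carlo error is comfortably
below the effect it certifies. All randomness flows through explicit seeds;
re-running any simulation with the same parameters reproduces its output bit
for bit, and `run_pipeline` writes a manifest (config hash, seed, R version)
alongside byte-stable stage outputs.

# Known limitations

* Single-generation parental assortment (no equilibrium dynastic structure).
* The additive channel mixture realizes second moments exactly but is not the
  unique coupling with those moments; tail dependence differs from a jointly
  Gaussian coupling.
* Closed-form correlation expectations are first-order approximations,
  degrading slowly as $|s|$ and $|r|$ grow jointly.
* Estimate contrasts (Z tests between $\gamma$, $\rho$, $\omega$) treat the
  estimates as independent; their dependence through shared instruments is
  acknowledged, not modelled.
* Binary/ordinal phenotypes are regressed linearly, mirroring the reference
  pipeline's convention rather than a measurement model.
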