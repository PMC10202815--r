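#' Pair two samples at a target correlation by Gaussian-copula rank matching
#'
#' Draws a latent bivariate normal sample at correlation `target_r`, then pairs
#' the `a`-side value of latent rank j with the `b`-side value of the latent
#' partner's rank. Marginal distributions are untouched; the realized Pearson
#' correlation of the pairing approaches `target_r` for approximately normal
#' margins (exactly rank-matched at `target_r = 1`).
#'
#' @param a,b numeric vectors of equal length (one value per candidate).
#' @param target_r desired correlation between `a` and the permuted `b`.
#' @param seed optional integer seed.
#' @return an integer permutation `p` (a bijection of `seq_along(b)`) such that
#'   couple i is `(a[i], b[p[i]])`.
#' @examples
#' a <- rnorm(1000); b <- rnorm(1000)
#' p <- assort_pairs(a, b, 0.5, seed = 1)
#' cor(a, b[p]) # about 0.5
#' @export
assort_pairs <- function(a, b, target_r, seed = NULL) {
  if (length(a) != length(b)) stop_invalid("a and b must have equal length")
  check_corr(target_r, "target_r")
  n <- length(a)
  with_seed(seed, {
    if (target_r == 1) {
      perm <- integer(n); perm[order(a)] <- order(b); return(perm)
    }
    if (target_r == -1) {
      perm <- integer(n); perm[order(a)] <- rev(order(b)); return(perm)
    }
    u <- stats::rnorm(n)
    v <- target_r * u + sqrt(1 - target_r^2) * stats::rnorm(n)
    perm <- integer(n)
    # candidate with rank r among a takes the slot of latent u with rank r
    perm[order(a)[rank(u, ties.method = "first")]] <-
      order(b)[rank(v, ties.method = "first")]
    perm
  })
}

# Mixture-of-channels couple formation.
#
# `vals_a`, `vals_b`: n x m matrices of the candidate assortment variables
# (columns, e.g. G, E, X) for the two sides; `r`: length-m vector of direct
# assortment coefficients. Couples are split into channels, one per nonzero
# r[j]; within channel j members are rank-matched on variable j alone with
# matching correlation rho_j = sign(r_j) * sum(|r|), channel share
# p_j = |r_j| / sum(|r|). The population cross-covariance between the two
# sides is then sum_j r_j * cov(v, V_j) cov(v, V_j)' / Var(V_j): each direct
# assortment contributes its own additive rank-one term, which is the additive
# decomposition of couple correlation the structural model assumes.
#
# Returns a permutation of side-b rows.
pair_by_channels <- function(vals_a, vals_b, r) {
  vals_a <- as.matrix(vals_a); vals_b <- as.matrix(vals_b)
  n <- nrow(vals_a)
  stopifnot(nrow(vals_b) == n, ncol(vals_b) == ncol(vals_a), length(r) == ncol(vals_a))
  s <- sum(abs(r))
  if (s == 0) return(sample.int(n))
  if (s > 1) stop_infeasible(
    "total direct assortment strength sum(|r|) = ", signif(s, 4),
    " exceeds 1; no single-variable matching mixture can realize these targets")
  active <- which(r != 0)
  # random channel assignment with expected shares |r_j|/s
  lab <- active[sample.int(length(active), n, replace = TRUE,
                           prob = abs(r[active]) / s)]
  perm <- integer(n)
  for (j in active) {
    idx <- which(lab == j)
    if (length(idx) < 2L) { perm[idx] <- idx; next }
    perm[idx] <- idx[assort_pairs(vals_a[idx, j], vals_b[idx, j], sign(r[j]) * s)]
  }
  perm
}
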