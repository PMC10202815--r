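#' Simulate unlinked biallelic genotypes
#'
#' Draws an `n` x `k` genotype dosage matrix under Hardy-Weinberg equilibrium:
#' entry \eqn{\in \{0,1,2\}} counts copies of the effect allele at each locus.
#' Loci are independent (no LD) unless `ld_rho` is set, in which case adjacent
#' loci share an AR(1) latent correlation `ld_rho` (useful for exercising
#' LD-based instrument pruning).
#'
#' @param n number of individuals (positive integer).
#' @param k number of loci (positive integer).
#' @param maf minor/effect allele frequency, a scalar or length-`k` vector with
#'   all values strictly inside (0, 1).
#' @param seed optional integer seed; the global RNG state is restored on exit.
#' @param ld_rho optional AR(1) correlation between the latent allele liabilities
#'   of adjacent loci (0 = independent loci, the default).
#' @return integer matrix of dosages with column names `snp1..snpk`.
#' @examples
#' g <- simulate_genotypes(100, 5, maf = 0.3, seed = 1)
#' colMeans(g) # about 2 * 0.3
#' @export
simulate_genotypes <- function(n, k, maf = 0.5, seed = NULL, ld_rho = 0) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop_invalid("n must be a positive count")
  if (!is.numeric(k) || length(k) != 1L || k < 1) stop_invalid("k must be a positive count")
  n <- as.integer(n); k <- as.integer(k)
  check_prob(maf, "maf")
  if (length(maf) == 1L) maf <- rep(maf, k)
  if (length(maf) != k) stop_invalid("maf must have length 1 or k")
  with_seed(seed, {
    if (ld_rho == 0) {
      g <- matrix(stats::rbinom(n * k, 2L, rep(maf, each = n)), nrow = n, ncol = k)
    } else {
      check_corr(ld_rho, "ld_rho")
      # two latent haplotype liability chains, thresholded at the allele frequency
      g <- matrix(0L, n, k)
      for (h in 1:2) {
        z <- matrix(stats::rnorm(n * k), n, k)
        for (j in 2:max(2L, k)) if (j <= k)
          z[, j] <- ld_rho * z[, j - 1L] + sqrt(1 - ld_rho^2) * z[, j]
        g <- g + (z < rep(stats::qnorm(maf), each = n))
      }
      storage.mode(g) <- "integer"
    }
    colnames(g) <- paste0("snp", seq_len(k))
    g
  })
}

#' Mendelian transmission of one offspring per parental pair
#'
#' Each offspring receives one allele per locus from each parent, drawn
#' uniformly from the parent's two alleles (dosage/2 transmission probability).
#'
#' @param geno_m,geno_f maternal and paternal dosage matrices (same dimensions).
#' @return offspring dosage matrix.
#' @export
mendelian_offspring <- function(geno_m, geno_f) {
  stopifnot(identical(dim(geno_m), dim(geno_f)))
  nk <- length(geno_m)
  off <- stats::rbinom(nk, 1L, geno_m / 2) + stats::rbinom(nk, 1L, geno_f / 2)
  off <- matrix(off, nrow = nrow(geno_m), dimnames = dimnames(geno_m))
  storage.mode(off) <- "integer"
  off
}

# standardized additive genetic score from a dosage matrix; columns scaled by
# their theoretical HWE sd, then the sum standardized empirically
genetic_score <- function(geno, maf) {
  sds <- sqrt(2 * maf * (1 - maf))
  raw <- geno %*% (1 / sds)
  zscale(drop(raw))
}
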