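# Shared small fixtures, built once per test run.

small_config <- function(seed = 7L, shares = c(additive = 0.5, dominance = 0,
                                               imprinting = 0, epistasis = 0,
                                               plot = 0.05, residual = 0.45),
                         n_snps = 400L, missing_rate = 0.1, ...) {
  sim_config(n_families = 18L, progeny_per_family = c(9L, 12L),
             n_maternal_parents = 25L, n_pollen_parents = 15L,
             n_snps = n_snps, missing_rate = missing_rate,
             variance_shares = shares, seed = seed, ...)
}

small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(small_config())
    cache
  }
})

# tiny hand-checkable phased genotype set: 3 individuals x 2 loci
toy_phased <- function() {
  mat <- rbind(c(0L, 1L), c(1L, 0L), c(0L, 0L))
  pat <- rbind(c(1L, 1L), c(0L, 0L), c(0L, 1L))
  dimnames(mat) <- dimnames(pat) <- list(c("i1", "i2", "i3"), c("s1", "s2"))
  geno_matrix(mat + pat, maternal = mat, paternal = pat)
}

random_psd <- function(n, seed) {
  set.seed(seed)
  M <- matrix(rnorm(n * (n + 2)), n)
  K <- tcrossprod(M) / (n + 2)
  dimnames(K) <- list(paste0("r", 1:n), paste0("r", 1:n))
  K
}
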