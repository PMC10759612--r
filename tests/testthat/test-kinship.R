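make_geno <- function(dosage, ...) {
  rownames(dosage) <- paste0("i", seq_len(nrow(dosage)))
  colnames(dosage) <- paste0("s", seq_len(ncol(dosage)))
  geno_matrix(dosage, ...)
}

test_that("SNP filters remove low-MAF and low-call-rate loci", {
  # 5 loci: normal, monomorphic, low MAF, low call rate, normal
  d <- cbind(c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 1L, 0L, 1L),
             rep(0L, 10),
             c(1L, rep(0L, 9)),                          # MAF 0.05 < 0.06
             c(0L, 1L, 2L, rep(NA, 7)),                  # 30% call rate
             c(2L, 1L, 0L, 1L, 2L, 1L, 0L, 1L, 2L, 1L))
  g <- make_geno(d)
  out <- filter_snps(g, maf_min = 0.06, call_rate_min = 0.40)
  expect_equal(ncol(out$dosage), 2L)
  rep <- attr(out, "filter_report")
  expect_equal(unname(rep["removed_low_call_rate"]), 1L)
  expect_equal(unname(rep["removed_low_maf"]), 2L)
  expect_error(filter_snps(g, maf_min = 0.9), "all loci removed")
})

test_that("random imputation draws Binomial(2, p) from observed frequencies", {
  n <- 10000
  d <- matrix(NA_integer_, n, 1)
  d[1:1000, 1] <- stats::rbinom(1000, 2, 0.3)
  g <- make_geno(d)
  p_obs <- mean(d[1:1000, 1]) / 2
  out <- impute_random(g, seed = 4)
  expect_identical(unname(out$dosage[1:1000, 1]), d[1:1000, 1])   # observed untouched
  expect_true(all(out$imputed[1001:n, 1]))
  imp <- out$dosage[1001:n, 1]
  se <- sqrt(2 * p_obs * (1 - p_obs) / length(imp))
  expect_lt(abs(mean(imp) - 2 * p_obs), 3 * se)
  # idempotent on complete data, error on fully missing locus
  expect_identical(impute_random(out, seed = 1)$dosage, out$dosage)
  g_bad <- make_geno(cbind(c(0L, 1L), c(NA_integer_, NA_integer_)))
  expect_error(impute_random(g_bad), "fully missing")
})

test_that("additive marker matrix centers dosages by 2p", {
  # p = 0.5 locus and p = 0.1 locus
  d <- cbind(c(2L, 0L, 1L, 1L), c(1L, 0L, 0L, 0L))
  M <- marker_matrix_additive(make_geno(d))
  p <- attr(M, "p")
  expect_equal(unname(p), c(0.5, 0.125))
  expect_equal(M[2, 1], -1)                       # A1A1 at p = 0.5
  expect_equal(M[1, 2], 1 - 2 * 0.125)            # heterozygote: 1 - 2p
  expect_equal(unname(colSums(M)), c(0, 0))       # exact centering identity
})

test_that("dominance marker matrix follows its three genotype classes", {
  d <- cbind(c(0L, 1L, 2L, 1L), c(2L, 0L, 0L, 0L))
  M <- marker_matrix_dominance(make_geno(d))
  p <- attr(M, "p")
  expect_equal(unname(p[1]), 0.5)
  expect_equal(M[, 1], c(-0.5, 0.5, -0.5, 0.5), ignore_attr = TRUE)
  # p = 0.25 locus: A2A2 entry -2(1-p)^2
  expect_equal(unname(p[2]), 0.25)
  expect_equal(M[1, 2], -2 * 0.75^2)
  # HWE mean is zero: p^2(-2q^2) + 2pq(2pq) + q^2(-2p^2) = 0 for any p
  for (pp in c(0.1, 0.3, 0.5)) {
    q <- 1 - pp
    expect_equal(pp^2 * (-2 * q^2) + 2 * pp * q * (2 * pp * q) + q^2 * (-2 * pp^2), 0)
  }
})

test_that("imprinting marker matrix encodes parental origin as +/-1", {
  g <- toy_phased()
  M <- marker_matrix_imprinting(g)
  # i1: locus1 maternal A1 / paternal A2 -> +1; locus2 homozygous A2A2 -> 0
  # i2: locus1 maternal A2 / paternal A1 -> -1; locus2 homozygous -> 0
  # i3: locus1 homozygous -> 0; locus2 maternal A1 / paternal A2 -> +1
  expect_equal(unname(M), rbind(c(1, 0), c(-1, 0), c(0, 1)), ignore_attr = TRUE)
  # swapping parental labels negates the matrix
  swapped <- geno_matrix(g$dosage, maternal = g$paternal, paternal = g$maternal)
  expect_equal(unname(marker_matrix_imprinting(swapped)), -unname(M),
               ignore_attr = TRUE)
  # all-homozygous individual gives an all-zero row
  expect_true(all(M[g$dosage != 1L] == 0))
})

test_that("unphased heterozygotes contribute zero and are reported", {
  g <- toy_phased()
  mat <- g$maternal; pat <- g$paternal
  mat[1, 1] <- NA_integer_; pat[1, 1] <- NA_integer_
  g2 <- geno_matrix(g$dosage, maternal = mat, paternal = pat)
  M <- marker_matrix_imprinting(g2)
  expect_equal(M[1, 1], 0)
  expect_equal(attr(M, "unresolved"), 1L)
  expect_error(marker_matrix_imprinting(g2, strict = TRUE), "resolve_phase")
})

test_that("pedigree-based phase resolution recovers dam-deducible sites", {
  # dam homozygous A1A1, progeny het -> maternal allele is A1
  d <- rbind(dam = c(0L, 2L, 1L), kid = c(1L, 1L, 1L))
  colnames(d) <- paste0("s", 1:3)
  g <- geno_matrix(d)
  ped <- data.frame(id = c("dam", "kid"), dam = c(NA, "dam"), sire = c(NA, NA))
  out <- resolve_phase(g, ped)
  expect_equal(out$maternal["kid", ], c(s1 = 0L, s2 = 1L, s3 = NA_integer_))
  expect_equal(out$paternal["kid", ], c(s1 = 1L, s2 = 0L, s3 = NA_integer_))
  rep <- attr(out, "phasing_report")
  # kid has 3 hets (2 dam-deduced), the dam's own het stays unresolved
  expect_equal(unname(rep["heterozygotes"]), 4L)
  expect_equal(unname(rep["resolved"]), 2L)
  expect_equal(unname(rep["unresolved"]), 2L)
})

test_that("phasing rate on synthetic data matches the dam-homozygous fraction", {
  dat <- small_dataset()
  g <- filter_snps(dat$genotypes_complete, maf_min = 0.01, call_rate_min = 0)
  founders <- simulate_founders(small_config())
  all_d <- rbind(founders$dosage[, colnames(g$dosage)], g$dosage)
  g_all <- geno_matrix(all_d)   # unphased view of progeny + parents
  out <- resolve_phase(g_all, dat$pedigree)
  rep <- attr(out, "phasing_report")
  # expected resolvable fraction among progeny hets: dam or sire homozygous
  prog <- dat$pedigree$id
  het <- g$dosage == 1L
  dam_h <- founders$dosage[dat$pedigree$dam, colnames(g$dosage)] != 1L
  sire_h <- founders$dosage[dat$pedigree$sire_fs, colnames(g$dosage)] != 1L
  expected <- sum(het & (dam_h | sire_h))
  resolved_prog <- sum(het & !is.na(out$maternal[prog, ]))
  expect_equal(resolved_prog, expected)
})

test_that("genomic relationship matrices match hand computations", {
  # two individuals, one locus, dosages (2, 0): p = 0.5, M_A = (1, -1),
  # denominator 2 * 0.25 = 0.5 -> G_A = [[2, -2], [-2, 2]]
  g <- make_geno(cbind(c(2L, 0L)))
  GA <- genomic_matrix(marker_matrix_additive(g), "A")
  expect_equal(unclass(GA), rbind(c(2, -2), c(-2, 2)), ignore_attr = TRUE)
  expect_equal(rel_kind(GA), "gen_A")
  # G_AA is the entrywise square
  GAA <- epistatic_matrix(GA)
  expect_equal(unclass(GAA), unclass(GA)^2, ignore_attr = TRUE)
  expect_equal(rel_kind(GAA), "gen_AA")
  expect_error(epistatic_matrix(GAA), "additive")
})

test_that("G_A diagonal averages one on HWE data and G_I vanishes without heterozygotes", {
  set.seed(9)
  n <- 300; m <- 2000
  p <- runif(m, 0.1, 0.5)
  d <- matrix(rbinom(n * m, 2, rep(p, each = n)), n)
  GA <- genomic_matrix(marker_matrix_additive(orient_minor(make_geno(d))), "A")
  expect_equal(mean(diag(GA)), 1, tolerance = 0.02)
  # all-homozygous population
  dh <- matrix(2L * rbinom(50 * 40, 1, 0.4), 50)
  dh[, colSums(dh) == 0] <- 2L  # avoid monomorphic-zero loci
  gh <- make_geno(dh)
  gh <- geno_matrix(gh$dosage, maternal = gh$dosage / 2L, paternal = gh$dosage / 2L)
  GI <- genomic_matrix(marker_matrix_imprinting(orient_minor(gh)), "I")
  expect_true(all(GI == 0))
})

test_that("Hadamard squares of PSD matrices stay PSD (Schur product theorem)", {
  for (s in 1:20) {
    K <- random_psd(12, seed = s)
    K <- rel_matrix(K, "gen_A")
    ev <- eigen(unclass(epistatic_matrix(K)), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
})

test_that("genomic G_A off-diagonals track pedigree A_A with slope near one", {
  cfg <- small_config(seed = 31, n_snps = 5000)
  dat <- simulate_dataset(cfg)
  gg <- filter_snps(dat$genotypes_complete, maf_min = 0.01, call_rate_min = 0)
  GA <- unclass(genomic_matrices(gg, kinds = "A")$A)
  A <- unclass(pedigree_additive(dat$pedigree, use_fs = TRUE, ids = dat$pedigree$id))
  lo <- lower.tri(GA)
  slope <- coef(lm(GA[lo] ~ A[lo]))[2]
  expect_equal(unname(slope), 1, tolerance = 0.1)
})
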