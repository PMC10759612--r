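test_that("founder genotypes follow Hardy-Weinberg proportions at the drawn frequencies", {
  cfg <- sim_config(n_families = 2, n_maternal_parents = 5000, n_pollen_parents = 5000,
                    n_snps = 100, maf_min = 0.05, seed = 11)
  fd <- simulate_founders(cfg)
  p <- colMeans(fd$dosage) / 2
  expect_true(all(p > 0))
  # per-locus heterozygosity within 3 binomial SEs of 2p(1-p)
  het <- colMeans(fd$dosage == 1L)
  expected <- 2 * p * (1 - p)
  se <- sqrt(expected * (1 - expected) / nrow(fd$dosage))
  expect_true(all(abs(het - expected) < 3.5 * se))
})

test_that("maf_min = 0.5 forces allele frequency 1/2 and genotype freqs (1/4, 1/2, 1/4)", {
  cfg <- sim_config(n_families = 2, n_maternal_parents = 4000, n_pollen_parents = 4000,
                    n_snps = 50, maf_min = 0.5, seed = 3)
  fd <- simulate_founders(cfg)
  p <- colMeans(fd$dosage) / 2
  expect_true(all(abs(p - 0.5) < 3 * sqrt(0.25 / (2 * nrow(fd$dosage)))))
  gf <- c(mean(fd$dosage == 0L), mean(fd$dosage == 1L), mean(fd$dosage == 2L))
  expect_equal(gf, c(0.25, 0.5, 0.25), tolerance = 0.02)
})

test_that("simulation is deterministic under a fixed seed", {
  d1 <- simulate_dataset(small_config(seed = 5))
  d2 <- simulate_dataset(small_config(seed = 5))
  expect_identical(d1$genotypes$dosage, d2$genotypes$dosage)
  expect_identical(d1$phenotypes$y, d2$phenotypes$y)
  d3 <- simulate_dataset(small_config(seed = 6))
  expect_false(identical(d1$phenotypes$y, d3$phenotypes$y))
})

test_that("progeny are Mendelian: every allele present in the corresponding parent", {
  dat <- small_dataset()
  fd <- simulate_founders(small_config())
  ped <- dat$pedigree
  g <- dat$genotypes_complete
  for (i in sample(nrow(ped), 10)) {
    dm <- ped$dam[i]; sr <- ped$sire_fs[i]
    expect_true(all(g$maternal[i, ] == fd$maternal[dm, ] |
                      g$maternal[i, ] == fd$paternal[dm, ]))
    expect_true(all(g$paternal[i, ] == fd$maternal[sr, ] |
                      g$paternal[i, ] == fd$paternal[sr, ]))
  }
  expect_true(all(ped$dam != ped$sire_fs))
  expect_true(all(is.na(ped$sire)))
})

test_that("maternal half-sibs have mean genomic additive relationship near 0.25", {
  cfg <- small_config(seed = 13, n_snps = 3000)
  dat <- simulate_dataset(cfg)
  gc <- filter_snps(dat$genotypes_complete, maf_min = 0.01, call_rate_min = 0)
  mats <- genomic_matrices(gc, kinds = "A")
  GA <- unclass(mats$A)
  ped <- dat$pedigree
  vals <- c()
  for (f in unique(ped$family)) {
    ids <- ped$id[ped$family == f]
    sibs <- ped[ped$family == f, ]
    # restrict to pairs with different sires: true half-sibs
    for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
      if (sibs$sire_fs[i] != sibs$sire_fs[j]) vals <- c(vals, GA[ids[i], ids[j]])
    }
  }
  expect_gt(length(vals), 100)
  # the minor shortfall from 0.25 reflects sample-frequency centering
  expect_lt(abs(mean(vals) - 0.25), 0.05)
})

test_that("field layout is a randomized complete block with unique coordinates", {
  dat <- small_dataset()
  lay <- dat$layout
  cfg <- dat$config
  tab <- table(lay$family, lay$block)
  expect_true(all(tab > 0))                      # every family in every block
  expect_equal(anyDuplicated(lay[c("row", "col")]), 0L)
  # nearest-neighbor distance on the planting grid equals the spacing
  expect_equal(min(dist(lay[c("x", "y")])), cfg$grid_spacing)
  # plots never exceed plot_size trees and hold a single family
  per_plot <- split(lay, lay$plot)
  expect_true(all(vapply(per_plot, nrow, 1L) <= cfg$plot_size))
  expect_true(all(vapply(per_plot, function(p) length(unique(p$family)), 1L) == 1L))
  # plot runs are contiguous within a row
  expect_true(all(vapply(per_plot, function(p) {
    length(unique(p$row)) == 1 && all(diff(sort(p$col)) == 1)
  }, logical(1))))
})

test_that("phenotype components realize their nominal variances over replicates", {
  shares <- c(additive = 0.2, dominance = 0, imprinting = 0, epistasis = 0.6,
              plot = 0, residual = 0.2)
  e_var <- replicate(30, {
    cfg <- sim_config(n_families = 12, progeny_per_family = c(8, 8),
                      n_maternal_parents = 15, n_pollen_parents = 10,
                      n_snps = 300, missing_rate = 0, variance_shares = shares,
                      seed = sample.int(1e6, 1))
    dat <- simulate_dataset(cfg)
    var(dat$truth$true_genetic_values$e)
  })
  # epistatic component variance ~ 0.6 within Monte-Carlo error of the mean
  se <- sd(e_var) / sqrt(length(e_var))
  expect_lt(abs(mean(e_var) - 0.6), 3 * se + 0.02)
})

test_that("null architecture gives phenotypes that are pure block + noise", {
  shares <- c(additive = 0, dominance = 0, imprinting = 0, epistasis = 0,
              plot = 0, residual = 1)
  dat <- simulate_dataset(small_config(seed = 21, shares = shares))
  tr <- dat$truth
  expect_true(all(unlist(tr$true_genetic_values) == 0))
  expect_true(all(tr$true_plot_effects == 0))
  adj <- adjust_phenotypes(dat$phenotypes, "y")
  expect_equal(sd(adj), 1, tolerance = 0.15)
})

test_that("missingness injection hits its rate and flags low-call loci", {
  dat <- small_dataset()
  g <- dat$genotypes_complete
  out <- inject_missingness(g, 0.177, seed = 2)
  expect_lt(abs(mean(is.na(out$dosage)) - 0.177), 0.005)
  out0 <- inject_missingness(g, 0, seed = 2)
  expect_identical(out0$dosage, g$dosage)
  out7 <- inject_missingness(g, 0.7, seed = 2)
  expect_gt(mean(attr(out7, "low_call_rate")), 0.5)
  expect_error(inject_missingness(g, 1), "rate")
})

test_that("phase bookkeeping is lossless: collapsing phased codes preserves dosages", {
  dat <- small_dataset()
  g <- dat$genotypes_complete
  expect_identical(collapse_phase(g), g$dosage)
  gm <- dat$genotypes
  d2 <- collapse_phase(gm)
  expect_identical(d2, gm$dosage)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_snps = 0), "degenerate")
  expect_error(sim_config(n_pollen_parents = 1), "degenerate")
  expect_error(sim_config(maf_min = 0), "maf_min")
  expect_error(sim_config(variance_shares = c(additive = 0.5, dominance = 0,
                                              imprinting = 0, epistasis = 0,
                                              plot = 0, residual = 0.4)),
               "sum to 1")
})
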