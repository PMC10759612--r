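test_that("block adjustment removes block means", {
  dat <- small_dataset()
  adj <- adjust_phenotypes(dat$phenotypes, "y")
  by_block <- tapply(adj[dat$phenotypes$id], dat$phenotypes$block, mean)
  expect_true(all(abs(by_block) < 1e-10))
  # block-effect-free data: adjustment is centering up to block noise
  ph <- dat$phenotypes
  set.seed(2); ph$y <- rnorm(nrow(ph))
  adj2 <- adjust_phenotypes(ph, "y")
  expect_equal(mean(adj2), 0, tolerance = 1e-12)
  # recovered block contrasts match the simulated fixed effects within 3 SEs
  fit <- lm(dat$phenotypes$y ~ factor(dat$phenotypes$block))
  be <- dat$truth$true_block_effects
  truth_contrast <- be[-1] - be[1]
  est <- coef(fit)[-1]
  se <- sqrt(diag(vcov(fit)))[-1]
  expect_true(all(abs(est - truth_contrast) < 3.5 * se))
})

test_that("fold plans partition ids into near-equal folds, reproducibly", {
  ids <- sprintf("T%03d", 1:661)
  plans <- make_folds(ids, k = 10, replicates = 10, seed = 5)
  for (r in 1:10) {
    pr <- plans[plans$replicate == r, ]
    expect_setequal(pr$id, ids)
    sizes <- table(pr$fold)
    expect_true(all(sizes %in% c(66L, 67L)))
    expect_equal(sum(sizes), 661L)
  }
  # deterministic under seed; different replicates differ
  plans2 <- make_folds(ids, k = 10, replicates = 10, seed = 5)
  expect_identical(plans, plans2)
  expect_false(identical(plans$id[plans$replicate == 1],
                         plans$id[plans$replicate == 2]))
  expect_error(make_folds(ids[1:5], k = 10), "more folds")
})

test_that("predictive ability is a guarded Pearson correlation", {
  x <- setNames(rnorm(50), paste0("i", 1:50))
  expect_equal(predictive_ability(x, x, names(x)), 1)
  expect_equal(predictive_ability(-x, x, names(x)), -1)
  # affine invariance
  expect_equal(predictive_ability(3 * x + 2, x, names(x)), 1)
  # null correlation for independent vectors
  set.seed(10)
  r <- replicate(100, {
    a <- setNames(rnorm(1000), paste0("i", 1:1000))
    b <- setNames(rnorm(1000), paste0("i", 1:1000))
    predictive_ability(a, b, names(a))
  })
  expect_lt(abs(mean(r)), 3 / sqrt(1000))
  expect_warning(predictive_ability(x[1:2], x, names(x)[1:2]), "undefined")
  const <- setNames(rep(1, 50), names(x))
  expect_warning(predictive_ability(const, x, names(x)), "undefined")
})

test_that("negligible genetic terms are dropped, additive always kept", {
  fake <- structure(list(sigma2 = c(plot = 0, a = 0.40, d = 0.01, i = 0.02,
                                    e = 0.55, residual = 0.02),
                         vcov_sigma2 = diag(0, 6)), class = "reml_fit")
  expect_setequal(select_optimal_terms(fake, 0.05 * 1.02), c("a", "e"))
  fake2 <- structure(list(sigma2 = c(plot = 0, a = 0.5, d = 0.01, i = 0.01,
                                     e = 0.01, residual = 0.47),
                          vcov_sigma2 = diag(0, 6)), class = "reml_fit")
  expect_equal(select_optimal_terms(fake2, 0.05), "a")
  expect_setequal(select_optimal_terms(fake, 0), c("a", "d", "i", "e"))
})

test_that("cross-validation scores genomic predictions and masks validation data", {
  cfg <- small_config(seed = 23, n_snps = 600)
  dat <- simulate_dataset(cfg)
  gen <- impute_random(filter_snps(dat$genotypes), seed = 2)
  mats <- genomic_matrices(gen, kinds = "A")
  names(mats) <- "a"
  folds <- make_folds(dat$phenotypes$id, k = 5, replicates = 1, seed = 3)
  cv <- run_cv(dat$phenotypes, "y", folds, method = "gblup", matrices = mats,
               include = "a", label = "GBLUP-A")
  expect_equal(nrow(cv), 5)
  expect_true(all(abs(cv$pa) <= 1, na.rm = TRUE))
  expect_gt(mean(cv$pa, na.rm = TRUE), 0)   # additive trait is predictable
  # masking correctness: validation phenotypes cannot influence predictions
  ph2 <- dat$phenotypes
  val1 <- folds$id[folds$replicate == 1 & folds$fold == 1]
  ph2$y[ph2$id %in% val1] <- 1e6   # arbitrary constants
  cv2 <- run_cv(ph2, "y", folds[folds$fold == 1, ], method = "gblup",
                matrices = mats, include = "a")
  # same training data -> identical predictions; PA differs only through the
  # (corrupted) adjusted phenotypes, so compare against a clean rescoring
  spec <- build_model(dat$phenotypes[!dat$phenotypes$id %in% val1, ], "y",
                      mats, include = "a")
  fit <- fit_model(spec)
  pred <- predict_genetic(fit, mats, val1, "additive_only")
  spec2 <- build_model(ph2[!ph2$id %in% val1, ], "y", mats, include = "a")
  fit2 <- fit_model(spec2)
  pred2 <- predict_genetic(fit2, mats, val1, "additive_only")
  expect_equal(pred, pred2, tolerance = 1e-10)
})

test_that("heritability-zero traits give predictive ability near zero", {
  shares <- c(additive = 0, dominance = 0, imprinting = 0, epistasis = 0,
              plot = 0, residual = 1)
  cfg <- small_config(seed = 29, shares = shares, n_snps = 400)
  dat <- simulate_dataset(cfg)
  gen <- impute_random(filter_snps(dat$genotypes), seed = 2)
  mats <- genomic_matrices(gen, kinds = "A")
  names(mats) <- "a"
  folds <- make_folds(dat$phenotypes$id, k = 5, replicates = 2, seed = 4)
  cv <- run_cv(dat$phenotypes, "y", folds, method = "gblup", matrices = mats)
  expect_lt(abs(mean(cv$pa, na.rm = TRUE)), 0.15)
})

test_that("paired comparison of CV results assigns stars", {
  base <- data.frame(replicate = rep(1:2, each = 5), fold = rep(1:5, 2),
                     n_val = 10, pa = seq(0.1, 0.5, length.out = 10))
  class(base) <- c("cv_result", "data.frame")
  same <- base
  out <- compare_pa(base, same)
  expect_equal(out$t_p, 1)
  expect_equal(out$stars, "ns")
  shifted <- base; shifted$pa <- base$pa + 0.2
  out2 <- compare_pa(shifted, base)
  expect_equal(out2$stars, "**")
  expect_equal(out2$mean_diff, 0.2)
  set.seed(1)
  noisy <- base; noisy$pa <- base$pa + rnorm(10, 0.2, 0.02)
  out3 <- compare_pa(noisy, base)
  expect_equal(out3$stars, "**")
  bad <- base[-1, ]
  expect_error(compare_pa(base, bad), "fold plans")
})
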