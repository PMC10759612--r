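#' Configuration for the open-pollinated progeny-trial simulator
#'
#' Defaults emulate the trial the package is designed around: 66
#' open-pollinated families of 9-12 trees each (about 661 trees in total)
#' from a clonal seed orchard, a randomized complete block design with 5
#' replications and 5-tree row plots on a 2 x 2 m grid, and 11,333 biallelic
#' SNPs with minimum minor allele frequency 0.05 and 17.7% missingness.
#'
#' @param n_families number of open-pollinated (known-dam) families.
#' @param progeny_per_family integer range of family sizes, sampled uniformly.
#' @param n_maternal_parents,n_pollen_parents sizes of the maternal and
#'   pollen-parent pools in the orchard.
#' @param n_snps number of biallelic SNPs.
#' @param maf_min lower bound of founder minor-allele frequencies, in (0, 0.5].
#' @param missing_rate missing-at-random genotype rate in `[0, 1)`.
#' @param n_blocks number of complete blocks (replications).
#' @param plot_size trees per row plot.
#' @param grid_spacing planting-grid spacing in metres.
#' @param variance_shares named non-negative shares of
#'   `total_phenotypic_variance` for `additive`, `dominance`, `imprinting`,
#'   `epistasis`, `plot` and `residual`; must sum to 1.
#' @param total_phenotypic_variance total phenotypic variance of the
#'   simulated trait.
#' @param block_effect_sd standard deviation of the fixed block effects.
#' @param grand_mean grand mean of the trait.
#' @param marker_effects if `TRUE`, genetic values are built from per-marker
#'   effect draws instead of multivariate-normal draws against the realized
#'   relationship matrices (robustness-study mode).
#' @param seed integer seed; identical seeds give identical datasets.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_families = 66L,
                       progeny_per_family = c(9L, 12L),
                       n_maternal_parents = 152L,
                       n_pollen_parents = 97L,
                       n_snps = 11333L,
                       maf_min = 0.05,
                       missing_rate = 0.177,
                       n_blocks = 5L,
                       plot_size = 5L,
                       grid_spacing = 2,
                       variance_shares = c(additive = 0.25, dominance = 0.05,
                                           imprinting = 0.05, epistasis = 0.15,
                                           plot = 0.05, residual = 0.45),
                       total_phenotypic_variance = 1,
                       block_effect_sd = 0.5,
                       grand_mean = 0,
                       marker_effects = FALSE,
                       seed = 1L) {
  comp <- c("additive", "dominance", "imprinting", "epistasis", "plot", "residual")
  if (!all(comp %in% names(variance_shares))) {
    stop("variance_shares must name: ", paste(comp, collapse = ", "))
  }
  variance_shares <- variance_shares[comp]
  if (any(variance_shares < 0) || abs(sum(variance_shares) - 1) > 1e-12) {
    stop("variance_shares must be non-negative and sum to 1 (within 1e-12)")
  }
  if (!(maf_min > 0 && maf_min <= 0.5)) stop("maf_min must lie in (0, 0.5]")
  if (!(missing_rate >= 0 && missing_rate < 1)) stop("missing_rate must lie in [0, 1)")
  if (n_families < 1 || n_snps < 1) stop("degenerate configuration: need >= 1 family and >= 1 SNP")
  if (n_maternal_parents < 2 || n_pollen_parents < 2) {
    stop("degenerate configuration: need >= 2 maternal and >= 2 pollen parents")
  }
  if (n_maternal_parents < n_families) stop("need at least one maternal parent per family")
  if (length(progeny_per_family) == 1) progeny_per_family <- rep(progeny_per_family, 2)
  if (total_phenotypic_variance <= 0) stop("total_phenotypic_variance must be > 0")
  structure(list(
    n_families = as.integer(n_families),
    progeny_per_family = as.integer(progeny_per_family),
    n_maternal_parents = as.integer(n_maternal_parents),
    n_pollen_parents = as.integer(n_pollen_parents),
    n_snps = as.integer(n_snps),
    maf_min = maf_min, missing_rate = missing_rate,
    n_blocks = as.integer(n_blocks), plot_size = as.integer(plot_size),
    grid_spacing = grid_spacing,
    variance_shares = variance_shares,
    total_phenotypic_variance = total_phenotypic_variance,
    block_effect_sd = block_effect_sd, grand_mean = grand_mean,
    marker_effects = isTRUE(marker_effects),
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate phased founder genotypes
#'
#' Founder allele frequencies are drawn uniformly on `[maf_min, 0.5]` and
#' founder genotypes in Hardy-Weinberg proportions; loci that come out
#' monomorphic across the founder pool are re-sampled so every realized MAF is
#' positive. Maternal and pollen-pool parents are generated together; row
#' names are prefixed `M` (maternal clones) and `P` (pollen parents).
#'
#' @param config a [sim_config()].
#' @return a phased `geno_matrix` of all founders, with attributes
#'   `maternal_ids`, `pollen_ids` and `founder_freq` (the drawn frequencies).
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(draw_seed(config$seed, 1L))
  n_f <- config$n_maternal_parents + config$n_pollen_parents
  m <- config$n_snps
  p <- stats::runif(m, config$maf_min, 0.5)
  ids <- c(paste0("M", seq_len(config$n_maternal_parents)),
           paste0("P", seq_len(config$n_pollen_parents)))
  draw <- function(pp) matrix(stats::rbinom(n_f * length(pp), 1L,
                                            rep(pp, each = n_f)), n_f)
  mat <- draw(p); pat <- draw(p)
  mono <- colSums(mat + pat) %in% c(0L, 2L * n_f)
  while (any(mono)) {
    p[mono] <- stats::runif(sum(mono), config$maf_min, 0.5)
    mat[, mono] <- draw(p[mono]); pat[, mono] <- draw(p[mono])
    mono <- colSums(mat + pat) %in% c(0L, 2L * n_f)
  }
  snps <- paste0("snp", seq_len(m))
  dimnames(mat) <- dimnames(pat) <- list(ids, snps)
  G <- geno_matrix(mat + pat, maternal = mat, paternal = pat)
  attr(G, "maternal_ids") <- ids[seq_len(config$n_maternal_parents)]
  attr(G, "pollen_ids") <- ids[-seq_len(config$n_maternal_parents)]
  attr(G, "founder_freq") <- p
  G
}

mendelian_gamete <- function(mat_alleles, pat_alleles) {
  pick <- stats::rbinom(length(mat_alleles), 1L, 0.5) == 1L
  out <- mat_alleles
  out[pick] <- pat_alleles[pick]
  out
}

#' Simulate open-pollinated families and Mendelian progeny genotypes
#'
#' Each family has a distinct dam from the maternal pool; each progeny draws
#' its pollen parent uniformly from the pollen pool (panmictic pollen cloud,
#' sire always different from the dam). Progeny genotypes are unlinked
#' Mendelian gametes from the (dam, sire) pair, with the maternal allele
#' recorded first so parental origin is known exactly. The returned pedigree
#' carries two views of paternity: `sire = NA` (the open-pollinated view,
#' before paternity assignment) and `sire_fs` (the full-sib view, after).
#'
#' @param config a [sim_config()].
#' @param founders output of [simulate_founders()].
#' @return list with `pedigree` (data.frame id, dam, sire, sire_fs, family)
#'   and `genotypes` (phased `geno_matrix` of the progeny).
#' @export
simulate_op_pedigree <- function(config, founders) {
  stopifnot(inherits(config, "sim_config"), inherits(founders, "geno_matrix"))
  set.seed(draw_seed(config$seed, 2L))
  dams_pool <- attr(founders, "maternal_ids")
  pollen <- attr(founders, "pollen_ids")
  if (is.null(dams_pool) || is.null(pollen)) stop("founders must come from simulate_founders()")
  dams <- sample(dams_pool, config$n_families)
  size_range <- seq(config$progeny_per_family[1], config$progeny_per_family[2])
  sizes <- if (length(size_range) == 1) rep(size_range, config$n_families)
           else sample(size_range, config$n_families, replace = TRUE)
  n <- sum(sizes)
  fam <- rep(seq_len(config$n_families), sizes)
  dam <- dams[fam]
  sire <- character(n)
  for (i in seq_len(n)) sire[i] <- sample(setdiff(pollen, dam[i]), 1L)
  ids <- sprintf("T%04d", seq_len(n))
  m <- config$n_snps
  mat <- matrix(0L, n, m); pat <- matrix(0L, n, m)
  fd <- founders
  for (i in seq_len(n)) {
    mat[i, ] <- mendelian_gamete(fd$maternal[dam[i], ], fd$paternal[dam[i], ])
    pat[i, ] <- mendelian_gamete(fd$maternal[sire[i], ], fd$paternal[sire[i], ])
  }
  dimnames(mat) <- dimnames(pat) <- list(ids, colnames(fd$dosage))
  ped <- data.frame(id = ids, dam = dam, sire = NA_character_,
                    sire_fs = sire, family = paste0("F", fam),
                    stringsAsFactors = FALSE)
  list(pedigree = ped, genotypes = geno_matrix(mat + pat, maternal = mat, paternal = pat))
}

#' Lay trees out on a randomized complete block grid
#'
#' Every family appears in every block; within a block, a family's trees are
#' grouped into contiguous row plots of at most `plot_size` trees, plots are
#' shuffled within the block, and blocks occupy disjoint bands of rows on a
#' common planting grid with `grid_spacing` metre spacing.
#'
#' @param config a [sim_config()].
#' @param pedigree pedigree data.frame from [simulate_op_pedigree()].
#' @return data.frame (id, family, block, plot, row, col, x, y).
#' @export
simulate_field_layout <- function(config, pedigree) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(draw_seed(config$seed, 3L))
  nb <- config$n_blocks
  fams <- split(pedigree$id, pedigree$family)
  if (any(lengths(fams) < nb)) {
    stop("family smaller than the number of blocks; cannot place it in every block")
  }
  per_block <- lapply(fams, function(ids) {
    ids <- sample(ids)
    split(ids, sort(rep_len(seq_len(nb), length(ids))))
  })
  plots_per_row <- max(4L, ceiling(sqrt(length(fams))))
  out <- vector("list", nb)
  row0 <- 0L
  for (b in seq_len(nb)) {
    units <- list()
    for (f in names(per_block)) {
      ids <- per_block[[f]][[b]]
      ng <- ceiling(length(ids) / config$plot_size)
      grp <- split(ids, rep(seq_len(ng), each = config$plot_size, length.out = length(ids)))
      for (g in grp) units <- c(units, list(list(family = f, ids = g)))
    }
    units <- units[sample(length(units))]
    rows_needed <- ceiling(length(units) / plots_per_row)
    recs <- lapply(seq_along(units), function(k) {
      u <- units[[k]]
      r <- row0 + (k - 1L) %/% plots_per_row + 1L
      c0 <- ((k - 1L) %% plots_per_row) * config$plot_size
      data.frame(id = u$ids, family = u$family, block = paste0("B", b),
                 plot = sprintf("B%d_%s_p%03d", b, u$family, k),
                 row = r, col = c0 + seq_along(u$ids),
                 stringsAsFactors = FALSE)
    })
    out[[b]] <- do.call(rbind, recs)
    row0 <- row0 + rows_needed
  }
  layout <- do.call(rbind, out)
  layout$x <- layout$col * config$grid_spacing
  layout$y <- layout$row * config$grid_spacing
  if (anyDuplicated(layout[c("row", "col")])) stop("internal error: duplicated grid positions")
  rownames(layout) <- NULL
  layout[match(pedigree$id, layout$id), , drop = FALSE]
}

draw_mvn <- function(n_draws, K, sigma2) {
  # one draw of N(0, sigma2 * K); K already bent to PSD
  ch <- chol(K)
  as.vector(crossprod(ch, stats::rnorm(nrow(K))) * sqrt(sigma2))
}

#' Simulate multi-component phenotypes on the trial
#'
#' Genetic values are drawn as zero-mean multivariate normals whose
#' covariances are the realized genomic relationship matrices of the
#' simulated progeny (additive `G_A`, dominance `G_D`, imprinting `G_I`,
#' epistatic `G_AA = G_A # G_A`) scaled by the component variances implied by
#' `variance_shares`; plot and residual effects are i.i.d. normal and block
#' effects are fixed draws. With `marker_effects = TRUE` the genetic values
#' are instead built mechanistically from per-marker effect draws — additive,
#' dominance and imprinting values as sums of marker effects, and the
#' epistatic value as a sum of random pairwise products of centered additive
#' marker codes (functional additive-by-additive epistasis, whose implied
#' covariance is the Hadamard square `G_A # G_A`). Matrices that turn out
#' numerically indefinite are bent by [bend_matrix()].
#'
#' @param config a [sim_config()].
#' @param genotypes complete (pre-missingness) phased progeny `geno_matrix`.
#' @param layout field layout from [simulate_field_layout()].
#' @return list with `phenotypes` (data.frame id, y, block, plot, row, col)
#'   and `truth` (true variances, per-individual component values, block and
#'   plot effects).
#' @export
simulate_phenotypes <- function(config, genotypes, layout) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "geno_matrix"))
  if (anyNA(genotypes$dosage)) stop("simulate phenotypes from complete genotypes (before missingness)")
  set.seed(draw_seed(config$seed, 4L))
  sh <- config$variance_shares
  s2 <- sh * config$total_phenotypic_variance
  n <- nrow(genotypes$dosage)
  ids <- geno_ids(genotypes)
  zero <- stats::setNames(numeric(n), ids)
  a <- d <- i_ <- e <- zero

  need_G <- c(additive = s2[["additive"]] > 0 || s2[["epistasis"]] > 0,
              dominance = s2[["dominance"]] > 0,
              imprinting = s2[["imprinting"]] > 0)
  # loci monomorphic in the progeny sample carry no signal; drop them here
  Gm <- orient_minor(genotypes)
  poly <- allele_freq(Gm) > 0
  Gm <- geno_matrix(Gm$dosage[, poly, drop = FALSE],
                    maternal = Gm$maternal[, poly, drop = FALSE],
                    paternal = Gm$paternal[, poly, drop = FALSE])
  GA <- GD <- GI <- NULL
  if (any(need_G) && !config$marker_effects) {
    if (need_G[["additive"]]) GA <- genomic_matrix(marker_matrix_additive(Gm), "A")
    if (need_G[["dominance"]]) GD <- genomic_matrix(marker_matrix_dominance(Gm), "D")
    if (need_G[["imprinting"]]) GI <- genomic_matrix(marker_matrix_imprinting(Gm), "I")
  }
  if (config$marker_effects) {
    scale_to <- function(v, target) {
      if (target == 0) return(zero)
      v <- v - mean(v)
      v * sqrt(target / max(stats::var(v), 1e-12))
    }
    if (s2[["additive"]] > 0) {
      MA <- marker_matrix_additive(Gm)
      a <- stats::setNames(scale_to(as.vector(MA %*% stats::rnorm(ncol(MA))), s2[["additive"]]), ids)
    }
    if (s2[["dominance"]] > 0) {
      MD <- marker_matrix_dominance(Gm)
      d <- stats::setNames(scale_to(as.vector(MD %*% stats::rnorm(ncol(MD))), s2[["dominance"]]), ids)
    }
    if (s2[["imprinting"]] > 0) {
      MI <- marker_matrix_imprinting(Gm)
      i_ <- stats::setNames(scale_to(as.vector(MI %*% stats::rnorm(ncol(MI))), s2[["imprinting"]]), ids)
    }
    if (s2[["epistasis"]] > 0) {
      MA <- marker_matrix_additive(Gm)
      n_pairs <- min(4000L, ncol(MA) * (ncol(MA) - 1L) %/% 2L)
      j1 <- sample.int(ncol(MA), n_pairs, replace = TRUE)
      j2 <- sample.int(ncol(MA), n_pairs, replace = TRUE)
      keep <- j1 != j2
      w <- stats::rnorm(sum(keep))
      ev <- as.vector((MA[, j1[keep], drop = FALSE] * MA[, j2[keep], drop = FALSE]) %*% w)
      e <- stats::setNames(scale_to(ev, s2[["epistasis"]]), ids)
    }
  } else {
    if (s2[["additive"]] > 0) a <- stats::setNames(draw_mvn(1, bend_matrix(unclass(GA)), s2[["additive"]]), ids)
    if (s2[["dominance"]] > 0) d <- stats::setNames(draw_mvn(1, bend_matrix(unclass(GD)), s2[["dominance"]]), ids)
    if (s2[["imprinting"]] > 0) i_ <- stats::setNames(draw_mvn(1, bend_matrix(unclass(GI)), s2[["imprinting"]]), ids)
  }
  if (s2[["epistasis"]] > 0 && !config$marker_effects) {
    if (is.null(GA)) GA <- genomic_matrix(marker_matrix_additive(Gm), "A")
    GAA <- epistatic_matrix(GA)
    e <- stats::setNames(draw_mvn(1, bend_matrix(unclass(GAA)), s2[["epistasis"]]), ids)
  }

  blocks <- sort(unique(layout$block))
  block_eff <- stats::setNames(stats::rnorm(length(blocks), 0, config$block_effect_sd), blocks)
  plots <- unique(layout$plot)
  plot_eff <- stats::setNames(stats::rnorm(length(plots), 0, sqrt(s2[["plot"]])), plots)
  eps <- stats::rnorm(n, 0, sqrt(s2[["residual"]]))

  lay <- layout[match(ids, layout$id), ]
  y <- config$grand_mean + block_eff[lay$block] + plot_eff[lay$plot] +
    a + d + i_ + e + eps
  pheno <- data.frame(id = ids, y = as.numeric(y), family = lay$family,
                      block = lay$block, plot = lay$plot,
                      row = lay$row, col = lay$col, stringsAsFactors = FALSE)
  truth <- list(true_variances = s2,
                true_genetic_values = list(a = a, d = d, i = i_, e = e),
                true_block_effects = block_eff,
                true_plot_effects = plot_eff,
                residuals = stats::setNames(eps, ids))
  list(phenotypes = pheno, truth = truth)
}

#' Mask genotypes missing-at-random
#'
#' Masks each entry independently with probability `rate` (dosage and phase
#' together) and flags loci whose call rate falls below 40%, the level at
#' which the SNP filter removes them.
#'
#' @param genotypes a `geno_matrix`.
#' @param rate missing rate in `[0, 1)`.
#' @param seed integer seed.
#' @return a `geno_matrix` with attribute `low_call_rate` (logical per locus).
#' @export
inject_missingness <- function(genotypes, rate, seed = 1L) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (rate >= 1 || rate < 0) stop("rate must lie in [0, 1)")
  if (rate == 0) {
    attr(genotypes, "low_call_rate") <- rep(FALSE, ncol(genotypes$dosage))
    return(genotypes)
  }
  set.seed(seed)
  d <- genotypes$dosage
  mask <- matrix(stats::runif(length(d)) < rate, nrow(d))
  d[mask] <- NA_integer_
  mat <- genotypes$maternal; pat <- genotypes$paternal
  if (!is.null(mat)) { mat[mask] <- NA_integer_; pat[mask] <- NA_integer_ }
  out <- geno_matrix(d, maternal = mat, paternal = pat)
  attr(out, "low_call_rate") <- colMeans(!is.na(d)) < 0.40
  out
}

#' Simulate a complete progeny-trial dataset
#'
#' Convenience wrapper running founder simulation, open-pollinated mating,
#' field layout, phenotype generation and missingness injection in order.
#'
#' @param config a [sim_config()].
#' @return list with `pedigree`, `genotypes` (with missingness),
#'   `genotypes_complete`, `layout`, `phenotypes`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  founders <- simulate_founders(config)
  fam <- simulate_op_pedigree(config, founders)
  layout <- simulate_field_layout(config, fam$pedigree)
  ph <- simulate_phenotypes(config, fam$genotypes, layout)
  gmiss <- inject_missingness(fam$genotypes, config$missing_rate,
                              seed = draw_seed(config$seed, 5L))
  list(pedigree = fam$pedigree, genotypes = gmiss,
       genotypes_complete = fam$genotypes, layout = layout,
       phenotypes = ph$phenotypes, truth = ph$truth, config = config)
}
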