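#' Filter SNPs on minor allele frequency and call rate
#'
#' Removes loci whose observed minor allele frequency is below `maf_min` or
#' whose call rate is below `call_rate_min` (defaults mirror common
#' genotyping-by-sequencing practice: MAF >= 0.05 and call rate >= 40%).
#'
#' @param G a `geno_matrix`.
#' @param maf_min minimum observed minor allele frequency.
#' @param call_rate_min minimum fraction of individuals with a call.
#' @return filtered `geno_matrix` with attribute `filter_report` giving
#'   counts removed by each rule.
#' @export
filter_snps <- function(G, maf_min = 0.05, call_rate_min = 0.40) {
  stopifnot(inherits(G, "geno_matrix"))
  call_rate <- colMeans(!is.na(G$dosage))
  p <- allele_freq(G)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  low_call <- call_rate < call_rate_min
  low_maf <- !low_call & maf < maf_min
  keep <- !(low_call | low_maf)
  if (!any(keep)) stop("all loci removed by filtering (", sum(low_maf), " low MAF, ",
                       sum(low_call), " low call rate)")
  out <- geno_matrix(G$dosage[, keep, drop = FALSE],
                     maternal = if (is.null(G$maternal)) NULL else G$maternal[, keep, drop = FALSE],
                     paternal = if (is.null(G$paternal)) NULL else G$paternal[, keep, drop = FALSE],
                     imputed = if (is.null(G$imputed)) NULL else G$imputed[, keep, drop = FALSE])
  attr(out, "filter_report") <- c(removed_low_maf = sum(low_maf),
                                  removed_low_call_rate = sum(low_call),
                                  kept = sum(keep))
  out
}

#' Random imputation of missing genotypes
#'
#' Each missing dosage is drawn independently as `Binomial(2, p_j)` with
#' `p_j` the locus's allele frequency among observed calls; observed entries
#' are never altered and imputed entries are flagged so that allele
#' frequencies used downstream can still be computed from observed calls
#' only. Imputed heterozygotes have unknown parental origin (phase `NA`).
#'
#' @param G a `geno_matrix`; every locus must have at least one observed call.
#' @param seed integer seed.
#' @return a complete `geno_matrix` with an `imputed` flag matrix.
#' @export
impute_random <- function(G, seed = 1L) {
  stopifnot(inherits(G, "geno_matrix"))
  miss <- is.na(G$dosage)
  if (!any(miss)) return(G)
  p <- allele_freq(G)
  if (anyNA(p)) stop("fully missing locus: filter on call rate before imputing")
  set.seed(seed)
  d <- G$dosage
  pj <- rep(p, each = nrow(d))[miss]
  d[miss] <- stats::rbinom(sum(miss), 2L, pj)
  mat <- G$maternal; pat <- G$paternal
  if (!is.null(mat)) {
    # imputed homozygotes have trivially known phase; imputed hets do not
    homo0 <- miss & d == 0L; homo2 <- miss & d == 2L
    mat[homo0] <- 0L; pat[homo0] <- 0L
    mat[homo2] <- 1L; pat[homo2] <- 1L
  }
  geno_matrix(d, maternal = mat, paternal = pat, imputed = miss)
}

marker_p <- function(G) {
  p <- allele_freq(G)
  if (any(is.na(p)) || any(p <= 0) || any(p > 0.5 + 1e-12)) {
    stop("marker matrices need observed minor allele frequencies in (0, 0.5]; ",
         "run orient_minor() and filter_snps() first")
  }
  p
}

#' Centered additive marker matrix
#'
#' Entry for individual i at locus j is `dosage - 2 p_j`, i.e. -2p, 1-2p,
#' 2-2p for the three genotype classes, with `p_j` the observed minor allele
#' frequency. Columns therefore sum to zero exactly when `p_j` is computed
#' from the same data.
#'
#' @param G complete, minor-allele-oriented `geno_matrix`.
#' @return numeric matrix `M_A` with attribute `p` (the frequencies used).
#' @export
marker_matrix_additive <- function(G) {
  if (anyNA(G$dosage)) stop("missing dosages: impute before building marker matrices")
  p <- marker_p(G)
  M <- sweep(G$dosage, 2L, 2 * p)
  attr(M, "p") <- p
  M
}

#' Dominance marker matrix
#'
#' Genotype classes map to `-2 p^2` (A1A1), `2 p (1 - p)` (heterozygote) and
#' `-2 (1 - p)^2` (A2A2), which has zero mean under Hardy-Weinberg
#' proportions at `p_j`.
#'
#' @inheritParams marker_matrix_additive
#' @return numeric matrix `M_D` with attribute `p`.
#' @export
marker_matrix_dominance <- function(G) {
  if (anyNA(G$dosage)) stop("missing dosages: impute before building marker matrices")
  p <- marker_p(G)
  n <- nrow(G$dosage)
  P <- matrix(p, n, length(p), byrow = TRUE)
  M <- matrix(0, n, length(p), dimnames = dimnames(G$dosage))
  d <- G$dosage
  M[d == 0L] <- (-2 * P^2)[d == 0L]
  M[d == 1L] <- (2 * P * (1 - P))[d == 1L]
  M[d == 2L] <- (-2 * (1 - P)^2)[d == 2L]
  attr(M, "p") <- p
  M
}

#' Imprinting (parent-of-origin) marker matrix
#'
#' Ordered heterozygotes map to +1 when the minor (counted) allele came from
#' the father (maternal A1, paternal A2) and -1 when it came from the mother;
#' homozygotes map to 0. Heterozygotes whose parental origin is unknown also
#' contribute 0 and are counted in the attribute `unresolved` — run
#' [resolve_phase()] first to maximise coverage.
#'
#' @inheritParams marker_matrix_additive
#' @param strict error (rather than zero-fill) on unphased heterozygotes.
#' @return numeric matrix `M_I` with attributes `p` and `unresolved` (count).
#' @export
marker_matrix_imprinting <- function(G, strict = FALSE) {
  if (anyNA(G$dosage)) stop("missing dosages: impute before building marker matrices")
  p <- marker_p(G)
  if (is.null(G$maternal)) stop("imprinting matrix needs parental-origin (phased) genotypes; ",
                                "see resolve_phase() for pedigree-based phasing")
  het <- G$dosage == 1L
  unres <- het & is.na(G$maternal)
  if (strict && any(unres)) {
    stop(sum(unres), " unphased heterozygotes; resolve_phase() can phase the ",
         "pedigree-deducible subset")
  }
  M <- matrix(0, nrow(G$dosage), ncol(G$dosage), dimnames = dimnames(G$dosage))
  plus <- het & !is.na(G$maternal) & G$maternal == 0L   # maternal A1, paternal A2
  minus <- het & !is.na(G$maternal) & G$maternal == 1L  # maternal A2, paternal A1
  M[plus] <- 1
  M[minus] <- -1
  attr(M, "p") <- p
  attr(M, "unresolved") <- sum(unres)
  M
}

#' Pedigree-based phase resolution for heterozygotes
#'
#' Assigns parental origin to heterozygous progeny genotypes where Mendelian
#' logic makes it unambiguous: a homozygous genotyped dam fixes the maternal
#' allele, and (in a full-sib pedigree view) a homozygous genotyped sire
#' fixes the paternal allele. Remaining heterozygotes stay unphased and later
#' contribute 0 to the imprinting marker matrix.
#'
#' @param G a `geno_matrix` that includes parents and progeny (or progeny
#'   only, with parents supplied via `parents`).
#' @param pedigree data.frame with columns `id`, `dam` and (optionally)
#'   `sire`/`sire_fs`; unknown parents `NA`.
#' @param parents optional separate `geno_matrix` holding parent genotypes.
#' @return `G` with maternal/paternal matrices filled where deducible and a
#'   `phasing_report` attribute (counts of heterozygotes resolved/unresolved).
#' @export
resolve_phase <- function(G, pedigree, parents = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  src <- if (is.null(parents)) G else parents
  n <- nrow(G$dosage); m <- ncol(G$dosage)
  mat <- G$maternal %||% matrix(NA_integer_, n, m, dimnames = dimnames(G$dosage))
  pat <- G$paternal %||% matrix(NA_integer_, n, m, dimnames = dimnames(G$dosage))
  homo <- !is.na(G$dosage) & G$dosage != 1L
  mat[homo] <- as.integer(G$dosage[homo] / 2L)
  pat[homo] <- as.integer(G$dosage[homo] / 2L)
  sire_col <- if (!is.null(pedigree$sire_fs)) "sire_fs" else "sire"
  ped <- pedigree[match(rownames(G$dosage), pedigree$id), , drop = FALSE]
  for (i in seq_len(n)) {
    het <- !is.na(G$dosage[i, ]) & G$dosage[i, ] == 1L & is.na(mat[i, ])
    if (!any(het)) next
    dam <- ped$dam[i]
    if (!is.na(dam) && dam %in% rownames(src$dosage)) {
      dg <- src$dosage[dam, ]
      fix <- het & !is.na(dg) & dg != 1L
      mat[i, fix] <- as.integer(dg[fix] / 2L)
      pat[i, fix] <- 1L - mat[i, fix]
      het <- het & !fix
    }
    sire <- ped[[sire_col]][i]
    if (any(het) && !is.na(sire) && sire %in% rownames(src$dosage)) {
      sg <- src$dosage[sire, ]
      fix <- het & !is.na(sg) & sg != 1L
      pat[i, fix] <- as.integer(sg[fix] / 2L)
      mat[i, fix] <- 1L - pat[i, fix]
    }
  }
  out <- geno_matrix(G$dosage, maternal = mat, paternal = pat, imputed = G$imputed)
  n_het <- sum(G$dosage == 1L, na.rm = TRUE)
  n_unres <- sum(G$dosage == 1L & is.na(mat), na.rm = TRUE)
  attr(out, "phasing_report") <- c(heterozygotes = n_het,
                                   resolved = n_het - n_unres,
                                   unresolved = n_unres)
  out
}

#' Genomic relationship matrix from a marker matrix
#'
#' `G = M M' / denom` with `denom = 2 * sum(p_j (1 - p_j))` for the additive
#' matrix and `sum((2 p_j (1 - p_j))^2)` for the dominance and imprinting
#' matrices, `p_j` being the observed minor allele frequencies carried by the
#' marker matrix.
#'
#' @param M marker matrix from one of the `marker_matrix_*` builders (must
#'   carry the `p` attribute).
#' @param kind `"A"`, `"D"` or `"I"`.
#' @return a `rel_matrix` of kind `gen_A`, `gen_D` or `gen_I`.
#' @export
genomic_matrix <- function(M, kind = c("A", "D", "I")) {
  kind <- match.arg(kind)
  p <- attr(M, "p")
  if (is.null(p)) stop("marker matrix must carry its allele frequencies (attribute 'p')")
  denom <- if (kind == "A") 2 * sum(p * (1 - p)) else sum((2 * p * (1 - p))^2)
  if (denom <= 0) stop("zero denominator: all loci monomorphic")
  G <- tcrossprod(M) / denom
  rel_matrix(G, kind = paste0("gen_", kind))
}

#' First-order epistatic relationship matrix (Hadamard square)
#'
#' `G_AA = G_A # G_A`, the cell-by-cell (Hadamard) product of the additive
#' genomic relationship matrix with itself; positive semidefinite by the
#' Schur product theorem.
#'
#' @param GA a `rel_matrix` of kind `gen_A` (or `ped_A`).
#' @return a `rel_matrix` of kind `gen_AA`.
#' @export
epistatic_matrix <- function(GA) {
  if (!inherits(GA, "rel_matrix") || !rel_kind(GA) %in% c("gen_A", "ped_A")) {
    stop("epistatic matrix is built from an additive relationship matrix")
  }
  rel_matrix(unclass(GA) * unclass(GA), kind = "gen_AA")
}

#' Build the full set of genomic relationship matrices
#'
#' Orients loci to the minor allele, builds `M_A`, `M_D`, `M_I`, and returns
#' the additive, dominance, imprinting and Hadamard epistatic relationship
#' matrices.
#'
#' @param G complete `geno_matrix` (imputed, filtered).
#' @param pedigree optional pedigree passed to [resolve_phase()] when phased
#'   entries are absent or incomplete.
#' @param kinds subset of `c("A", "D", "I", "AA")`.
#' @return named list of `rel_matrix` objects (`A`, `D`, `I`, `AA`).
#' @export
genomic_matrices <- function(G, pedigree = NULL, kinds = c("A", "D", "I", "AA")) {
  Gm <- orient_minor(G)
  if (("I" %in% kinds) && !is.null(pedigree)) Gm <- resolve_phase(Gm, pedigree)
  out <- list()
  if (any(c("A", "AA") %in% kinds)) {
    GA <- genomic_matrix(marker_matrix_additive(Gm), "A")
    if ("A" %in% kinds) out$A <- GA
    if ("AA" %in% kinds) out$AA <- epistatic_matrix(GA)
  }
  if ("D" %in% kinds) out$D <- genomic_matrix(marker_matrix_dominance(Gm), "D")
  if ("I" %in% kinds) out$I <- genomic_matrix(marker_matrix_imprinting(Gm), "I")
  out[intersect(c("A", "D", "I", "AA"), kinds)]
}
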