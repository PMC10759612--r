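#' larchgp: genetic dissection and genomic prediction for open-pollinated
#' progeny trials
#'
#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

utils::globalVariables(c("model", "pa"))

#' Bend a covariance matrix to numerical positive semidefiniteness
#'
#' Relationship matrices assembled from finite marker samples (notably the
#' dominance and imprinting matrices) can be numerically indefinite. Before a
#' matrix is used as the covariance of a random effect it is "bent" by adding
#' a small ridge, `1e-8 * mean(diag(K))` per pass, until its smallest
#' eigenvalue is at least `min_eigen`.
#'
#' @param K symmetric matrix.
#' @param min_eigen smallest acceptable eigenvalue (default `1e-10`).
#' @param quiet suppress the message reporting the ridge added.
#' @return the bent matrix; attribute `"ridge"` records the total ridge added
#'   (0 if none was needed).
#' @export
bend_matrix <- function(K, min_eigen = 1e-10, quiet = TRUE) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  ridge <- 0
  step <- 1e-8 * mean(diag(K))
  if (step <= 0) step <- 1e-8
  ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  while (ev < min_eigen) {
    K <- K + diag(step, nrow(K))
    ridge <- ridge + step
    step <- step * 10
    ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  }
  if (ridge > 0 && !quiet) {
    message(sprintf("bend_matrix: added ridge %.3g to reach min eigenvalue %.3g", ridge, ev))
  }
  attr(K, "ridge") <- ridge
  K
}

#' Labelled relationship matrix
#'
#' Thin wrapper that validates symmetry and attaches a `kind` tag
#' (`"ped_A"`, `"ped_D"`, `"gen_A"`, `"gen_D"`, `"gen_I"`, `"gen_AA"`,
#' `"kernel"`) to a square matrix with individual ids as dimnames.
#'
#' @param K square numeric matrix with rownames = individual ids.
#' @param kind one of the recognised kind tags.
#' @return the matrix with class `rel_matrix` and attribute `kind`.
#' @export
rel_matrix <- function(K, kind) {
  kinds <- c("ped_A", "ped_D", "gen_A", "gen_D", "gen_I", "gen_AA", "kernel")
  kind <- match.arg(kind, kinds)
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  if (is.null(rownames(K))) stop("relationship matrix must carry individual ids as rownames")
  if (max(abs(K - t(K))) > 1e-10) stop("relationship matrix not symmetric within 1e-10")
  K <- (K + t(K)) / 2
  colnames(K) <- rownames(K)
  structure(K, kind = kind, class = c("rel_matrix", "matrix", "array"))
}

#' @export
print.rel_matrix <- function(x, ...) {
  cat(sprintf("<rel_matrix kind=%s, %d individuals>\n", attr(x, "kind"), nrow(x)))
  if (nrow(x) <= 8) print(unclass(x)[, , drop = FALSE]) else utils::str(unclass(x))
  invisible(x)
}

rel_kind <- function(K) attr(K, "kind")

#' Phased genotype container
#'
#' Stores an individuals-by-SNP dosage matrix (counts of the A2 allele, values
#' 0/1/2 or `NA` for missing) plus, optionally, the parental-origin split:
#' `maternal` and `paternal` 0/1 allele matrices (maternal allele listed
#' first). Where phase is unknown for a heterozygote both allele matrices hold
#' `NA` while the dosage is still 1.
#'
#' @param dosage integer matrix, rows = individuals (rownames = ids),
#'   columns = SNPs.
#' @param maternal,paternal optional 0/1 matrices of parental-origin alleles.
#' @param imputed optional logical matrix flagging imputed entries.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, maternal = NULL, paternal = NULL, imputed = NULL) {
  stopifnot(is.matrix(dosage))
  if (is.null(rownames(dosage))) stop("dosage needs individual ids as rownames")
  if (is.null(colnames(dosage))) colnames(dosage) <- paste0("snp", seq_len(ncol(dosage)))
  ok <- dosage %in% c(0L, 1L, 2L) | is.na(dosage)
  if (!all(ok)) stop("dosage entries must be 0, 1, 2 or NA")
  if (!is.null(maternal)) {
    stopifnot(all(dim(maternal) == dim(dosage)), all(dim(paternal) == dim(dosage)))
    both <- !is.na(maternal) & !is.na(paternal)
    if (any(both & !is.na(dosage) & (maternal + paternal) != dosage)) {
      stop("phased alleles do not collapse to the unordered dosage")
    }
  }
  structure(list(dosage = dosage, maternal = maternal, paternal = paternal,
                 imputed = imputed),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix: %d individuals x %d SNPs, %.1f%% missing, %s>\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage)),
              if (is.null(x$maternal)) "unphased" else "phased"))
  invisible(x)
}

#' Individual ids of a genotype container
#' @param G a `geno_matrix`.
#' @return character vector of ids.
#' @export
geno_ids <- function(G) rownames(G$dosage)

#' Collapse phased alleles to unordered dosages
#'
#' Checks the bookkeeping invariant that the phased representation is lossless
#' with respect to allele counts: where both parental alleles are recorded
#' their sum is returned, elsewhere the stored dosage.
#'
#' @param G a `geno_matrix`.
#' @return integer dosage matrix.
#' @export
collapse_phase <- function(G) {
  d <- G$dosage
  if (!is.null(G$maternal)) {
    both <- !is.na(G$maternal) & !is.na(G$paternal)
    d[both] <- G$maternal[both] + G$paternal[both]
  }
  d
}

#' Observed allele frequency of the counted (A2) allele per locus
#' @param G a `geno_matrix`.
#' @param observed_only ignore imputed entries when `TRUE` (default) and an
#'   imputation flag is present.
#' @return numeric vector of per-locus frequencies.
#' @export
allele_freq <- function(G, observed_only = TRUE) {
  d <- G$dosage
  if (observed_only && !is.null(G$imputed)) d[G$imputed] <- NA
  colMeans(d, na.rm = TRUE) / 2
}

#' Re-orient loci so the counted allele is the minor allele
#'
#' Loci where the counted A2 allele has observed frequency above 0.5 are
#' flipped (dosage `2 - d`, parental alleles `1 - a`), so that the `p_j` used
#' in marker-matrix denominators is always the observed minor-allele
#' frequency.
#'
#' @param G a `geno_matrix`.
#' @return a `geno_matrix` with attribute `"flipped"` marking flipped loci.
#' @export
orient_minor <- function(G) {
  p <- allele_freq(G)
  flip <- !is.na(p) & p > 0.5
  if (any(flip)) {
    G$dosage[, flip] <- 2L - G$dosage[, flip]
    if (!is.null(G$maternal)) {
      G$maternal[, flip] <- 1L - G$maternal[, flip]
      G$paternal[, flip] <- 1L - G$paternal[, flip]
    }
  }
  attr(G, "flipped") <- flip
  G
}

draw_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483629L
}
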