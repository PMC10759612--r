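order_pedigree <- function(ped) {
  # topological order: parents before offspring; detects cycles
  ids <- ped$id
  n <- length(ids)
  dam <- match(ped$dam, ids)
  sire <- match(ped$sire, ids)
  placed <- rep(FALSE, n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(dam) | placed[ifelse(is.na(dam), 1L, dam)]) &
      (is.na(sire) | placed[ifelse(is.na(sire), 1L, sire)])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed)) stop("pedigree contains a cycle or an individual that is its own ancestor")
  ord
}

normalize_pedigree <- function(ped, use_fs = FALSE) {
  sire_col <- if (use_fs && !is.null(ped$sire_fs)) "sire_fs" else "sire"
  out <- data.frame(id = as.character(ped$id),
                    dam = as.character(ped$dam),
                    sire = as.character(ped[[sire_col]]),
                    stringsAsFactors = FALSE)
  # founders referenced only as parents get their own records
  parents <- setdiff(stats::na.omit(c(out$dam, out$sire)), out$id)
  if (length(parents)) {
    out <- rbind(data.frame(id = parents, dam = NA_character_,
                            sire = NA_character_, stringsAsFactors = FALSE), out)
  }
  out[order_pedigree(out), , drop = FALSE]
}

#' Pedigree-based additive (numerator) relationship matrix
#'
#' Tabular method: `A_ii = 1 + A(dam_i, sire_i) / 2` and
#' `A_ij = (A(j, dam_i) + A(j, sire_i)) / 2` processing individuals in
#' topological order; unknown parents contribute 0. In an open-pollinated
#' pedigree (unknown sires) maternal half-sibs get off-diagonals of 0.25.
#'
#' @param pedigree data.frame with columns `id`, `dam`, `sire` (and
#'   optionally `sire_fs`); unknown parents `NA`.
#' @param use_fs use the reconstructed full-sib paternity column `sire_fs`
#'   when present.
#' @param ids optional subset/order of individuals for the returned matrix.
#' @return a `rel_matrix` of kind `ped_A` over all pedigree members (or
#'   `ids`).
#' @export
pedigree_additive <- function(pedigree, use_fs = FALSE, ids = NULL) {
  ped <- normalize_pedigree(pedigree, use_fs = use_fs)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  dam <- match(ped$dam, ped$id)
  sire <- match(ped$sire, ped$id)
  for (i in seq_len(n)) {
    di <- dam[i]; si <- sire[i]
    if (i > 1) {
      for (j in seq_len(i - 1L)) {
        aij <- 0
        if (!is.na(di)) aij <- aij + A[j, di]
        if (!is.na(si)) aij <- aij + A[j, si]
        A[i, j] <- A[j, i] <- aij / 2
      }
    }
    A[i, i] <- 1 + if (!is.na(di) && !is.na(si)) A[di, si] / 2 else 0
  }
  out <- rel_matrix(A, "ped_A")
  if (!is.null(ids)) out <- rel_matrix(unclass(out)[ids, ids, drop = FALSE], "ped_A")
  out
}

#' Pedigree-based dominance relationship matrix
#'
#' `D_ij = (A(s_i, s_j) A(d_i, d_j) + A(s_i, d_j) A(d_i, s_j)) / 4` with
#' `D_ii = 1`; any pair involving an unknown parent gets 0. Full sibs from
#' unrelated non-inbred parents get 0.25; half sibs and parent-offspring
#' pairs get 0.
#'
#' @inheritParams pedigree_additive
#' @param A optional precomputed `ped_A` matrix over the full pedigree (built
#'   internally when missing).
#' @return a `rel_matrix` of kind `ped_D`.
#' @export
pedigree_dominance <- function(pedigree, use_fs = FALSE, A = NULL, ids = NULL) {
  ped <- normalize_pedigree(pedigree, use_fs = use_fs)
  if (is.null(A)) A <- pedigree_additive(pedigree, use_fs = use_fs)
  if (!inherits(A, "rel_matrix") || rel_kind(A) != "ped_A") {
    stop("A must be a pedigree additive relationship matrix")
  }
  A <- unclass(A)
  n <- nrow(ped)
  D <- diag(1, n)
  dimnames(D) <- list(ped$id, ped$id)
  known <- !is.na(ped$dam) & !is.na(ped$sire)
  idx <- which(known)
  for (ii in seq_along(idx)) {
    i <- idx[ii]
    si <- ped$sire[i]; di <- ped$dam[i]
    for (jj in seq_len(ii - 1L)) {
      j <- idx[jj]
      sj <- ped$sire[j]; dj <- ped$dam[j]
      val <- (A[si, sj] * A[di, dj] + A[si, dj] * A[di, sj]) / 4
      D[i, j] <- D[j, i] <- val
    }
  }
  out <- rel_matrix(D, "ped_D")
  if (!is.null(ids)) out <- rel_matrix(unclass(out)[ids, ids, drop = FALSE], "ped_D")
  out
}
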