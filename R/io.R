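# Delimited readers/writers for the trial's tabular formats. Genotypes are
# stored individuals x SNPs with phased codes "0|0, 0|1, 1|0, 1|1" (maternal
# allele first), unphased "0/1/2", and "." for missing.

#' Write genotypes to a delimited matrix
#'
#' @param G a `geno_matrix`.
#' @param path output file.
#' @param sep field separator (default tab).
#' @export
write_genotypes <- function(G, path, sep = "\t") {
  d <- G$dosage
  out <- matrix(as.character(d), nrow(d), ncol(d))
  if (!is.null(G$maternal)) {
    ph <- !is.na(G$maternal)
    out[ph] <- paste0(G$maternal[ph], "|", G$paternal[ph])
  }
  out[is.na(d)] <- "."
  dimnames(out) <- dimnames(d)
  utils::write.table(out, path, sep = sep, quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read genotypes from a delimited matrix
#'
#' Accepts phased codes (`0|1`), unphased dosages (`0`, `1`, `2`) and `.`
#' for missing, as written by [write_genotypes()].
#'
#' @param path input file.
#' @param sep field separator.
#' @return a `geno_matrix`.
#' @export
read_genotypes <- function(path, sep = "\t") {
  raw <- as.matrix(utils::read.table(path, sep = sep, header = TRUE,
                                     row.names = 1, check.names = FALSE,
                                     colClasses = "character"))
  phased <- grepl("|", raw, fixed = TRUE)
  mat <- pat <- matrix(NA_integer_, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  d <- matrix(NA_integer_, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  if (any(phased)) {
    mat[phased] <- as.integer(substr(raw[phased], 1, 1))
    pat[phased] <- as.integer(substr(raw[phased], 3, 3))
    d[phased] <- mat[phased] + pat[phased]
  }
  plain <- !phased & raw != "."
  d[plain] <- as.integer(raw[plain])
  homo <- plain & (d == 0L | d == 2L)
  mat[homo] <- as.integer(d[homo] / 2L)
  pat[homo] <- mat[homo]
  if (all(is.na(mat))) mat <- pat <- NULL
  geno_matrix(d, maternal = mat, paternal = pat)
}

#' Read genotypes from a VCF file
#'
#' Uses the vcfR package to extract the GT field; phased separators (`|`)
#' are honoured as maternal|paternal order.
#'
#' @param path VCF file.
#' @return a `geno_matrix` (individuals x SNPs).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) stop("read_genotypes_vcf needs vcfR")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)         # SNPs x individuals
  gt <- t(gt)
  phased <- !is.na(gt) & grepl("|", gt, fixed = TRUE)
  mat <- pat <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  a1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
  d[] <- a1 + a2
  mat[phased] <- a1[phased]
  pat[phased] <- a2[phased]
  homo <- !is.na(d) & d != 1L
  mat[homo] <- as.integer(d[homo] / 2L)
  pat[homo] <- mat[homo]
  geno_matrix(d, maternal = mat, paternal = pat)
}

#' Write a pedigree to CSV
#'
#' @param pedigree pedigree data.frame.
#' @param path output file.
#' @param view `"op"` writes unknown sires (`NA`); `"fs"` writes the
#'   reconstructed `sire_fs` column as `sire`.
#' @export
write_pedigree <- function(pedigree, path, view = c("op", "fs")) {
  view <- match.arg(view)
  out <- data.frame(id = pedigree$id, dam = pedigree$dam,
                    sire = if (view == "fs" && !is.null(pedigree$sire_fs))
                      pedigree$sire_fs else pedigree$sire)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a relationship matrix as labelled CSV
#' @param K a `rel_matrix`.
#' @param path output file.
#' @export
write_rel_matrix <- function(K, path) {
  utils::write.csv(unclass(K), path)
  invisible(path)
}

#' Read a relationship matrix from labelled CSV
#' @param path input file.
#' @param kind kind tag to attach.
#' @return a `rel_matrix`.
#' @export
read_rel_matrix <- function(path, kind = "gen_A") {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  rel_matrix(m, kind)
}
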