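#' Stem volume from diameter and height
#'
#' Regional larch volume equation: `V = 0.0592372 * DBH^2 * H^0.98098926`,
#' with DBH in centimetres, height in metres and volume in cubic decimetres.
#'
#' @param dbh diameter at breast height (cm), > 0.
#' @param height tree height (m), > 0.
#' @return stem volume in dm^3.
#' @export
#' @examples
#' stem_volume(10, 10)
stem_volume <- function(dbh, height) {
  if (any(dbh <= 0, na.rm = TRUE) || any(height <= 0, na.rm = TRUE)) {
    stop("dbh and height must be strictly positive")
  }
  0.0592372 * dbh^2 * height^0.98098926
}

#' Hegyi competition index on a square planting grid
#'
#' `CI_i = sum_j (DBH_j / DBH_i) / D_ij` over the first-order neighbours of
#' the focal tree (at most 8). On the planting grid the distance is `spacing`
#' for row/column neighbours and `spacing * sqrt(2)` for diagonal neighbours.
#' Edge and corner trees simply use the neighbours that exist.
#'
#' @param focal list or one-row data.frame with `dbh`, `row`, `col`.
#' @param neighbors data.frame with columns `dbh`, `row`, `col`; every row
#'   must be at Chebyshev distance 1 from the focal tree.
#' @param spacing grid spacing in metres (default 2).
#' @return non-negative competition index.
#' @export
hegyi_ci <- function(focal, neighbors, spacing = 2) {
  if (focal$dbh <= 0) stop("focal DBH must be > 0")
  if (nrow(neighbors) < 1 || nrow(neighbors) > 8) stop("need 1 to 8 first-order neighbors")
  dr <- abs(neighbors$row - focal$row)
  dc <- abs(neighbors$col - focal$col)
  if (any(pmax(dr, dc) != 1)) stop("all neighbors must be first-order (Chebyshev distance 1)")
  dist <- ifelse(dr == 1 & dc == 1, spacing * sqrt(2), spacing)
  sum((neighbors$dbh / focal$dbh) / dist)
}

#' Hegyi competition index for every tree in a layout
#'
#' @param trees data.frame with columns `id`, `dbh`, `row`, `col`.
#' @param spacing grid spacing in metres.
#' @return named numeric vector of competition indices.
#' @export
hegyi_ci_all <- function(trees, spacing = 2) {
  idx <- paste(trees$row, trees$col)
  pos <- stats::setNames(seq_len(nrow(trees)), idx)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  out <- stats::setNames(numeric(nrow(trees)), trees$id)
  for (i in seq_len(nrow(trees))) {
    key <- paste(trees$row[i] + offs$dr, trees$col[i] + offs$dc)
    j <- pos[key]
    j <- j[!is.na(j)]
    if (!length(j)) { out[i] <- NA_real_; next }
    out[i] <- hegyi_ci(trees[i, ], trees[j, , drop = FALSE], spacing)
  }
  out
}

#' Descriptive statistics for a trait
#'
#' Mean, sample standard deviation (n - 1 denominator), minimum, maximum and
#' the coefficient of variation `CV = sd / mean * 100` in percent. Missing
#' values are skipped. When the mean is not positive the CV is flagged
#' undefined (`NA` with attribute `cv_undefined`).
#'
#' @param values numeric vector with at least 2 non-missing entries.
#' @return data.frame with columns mean, sd, min, max, cv_percent.
#' @export
describe_trait <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop("need at least 2 non-missing values")
  m <- mean(v); s <- stats::sd(v)
  cv <- if (m > 0) s / m * 100 else NA_real_
  out <- data.frame(mean = m, sd = s, min = min(v), max = max(v), cv_percent = cv)
  if (m <= 0) attr(out, "cv_undefined") <- TRUE
  out
}

#' Coefficient of variation in percent from summary statistics
#'
#' @param mean trait mean (> 0).
#' @param sd trait standard deviation.
#' @return `sd / mean * 100`.
#' @export
cv_percent <- function(mean, sd) {
  if (any(mean <= 0)) stop("CV undefined for non-positive mean")
  sd / mean * 100
}

#' Percentage of validated SNP calls
#'
#' Simple validation-rate arithmetic for genotyping quality control: the
#' share of independently re-sequenced SNPs whose calls were confirmed.
#'
#' @param n_validated number of confirmed SNPs.
#' @param n_selected number of SNPs re-sequenced.
#' @return percentage in `[0, 100]`.
#' @export
validation_rate <- function(n_validated, n_selected) {
  stopifnot(n_selected > 0, n_validated >= 0, n_validated <= n_selected)
  n_validated / n_selected * 100
}

#' Table of descriptive statistics for several traits
#'
#' @param pheno data.frame of phenotypes.
#' @param traits character vector of column names.
#' @return data.frame, one row per trait.
#' @export
describe_traits <- function(pheno, traits) {
  rows <- lapply(traits, function(tr) {
    cbind(trait = tr, describe_trait(pheno[[tr]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
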