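#' Assemble a mixed-model specification for a trait
#'
#' Builds the fixed-effect design (grand mean + block dummies), the plot
#' random term (identity covariance over plot levels) and one genetic random
#' term per requested label, each bound to its relationship matrix.
#' Individuals missing the trait are dropped from the response and from every
#' design. Model families map onto `include` sets: additive only (`"a"`),
#' additive + dominance (`c("a","d")`), up to the full additive + dominance +
#' imprinting + epistasis model (`c("a","d","i","e")`); pedigree or genomic
#' matrices give the pedigree-based and genomic flavours respectively.
#'
#' @param pheno data.frame with columns `id`, the trait, `block`, `plot`.
#' @param trait trait column name.
#' @param matrices named list of `rel_matrix` objects; names must cover the
#'   requested genetic labels (`a`, `d`, `i`, `e`).
#' @param include character subset of `c("plot", "a", "d", "i", "e")`;
#'   `"plot"` is added automatically when a plot column is present.
#' @param use_plot set `FALSE` to omit the plot random term even when a plot
#'   column exists (e.g. for data generated without plot effects).
#' @return list of class `model_spec` with `y`, `X`, `terms` (named list of
#'   n x n covariance matrices), `qvec`, `ids`, `trait`, `labels`.
#' @export
build_model <- function(pheno, trait, matrices, include = c("a"), use_plot = TRUE) {
  stopifnot(trait %in% names(pheno), "id" %in% names(pheno))
  keep <- !is.na(pheno[[trait]])
  ph <- pheno[keep, , drop = FALSE]
  ids <- as.character(ph$id)
  y <- as.numeric(ph[[trait]])
  if (!"block" %in% names(ph)) stop("phenotype table needs a block column")
  blocks <- factor(ph$block)
  if (nlevels(blocks) < 2) stop("need at least 2 blocks for the fixed-effect design")
  X <- stats::model.matrix(~blocks)
  colnames(X) <- c("(Intercept)", paste0("block_", levels(blocks)[-1]))
  glabels <- setdiff(include, "plot")
  terms <- list()
  qvec <- integer(0)
  if (use_plot && "plot" %in% names(ph)) {
    Zp <- stats::model.matrix(~0 + factor(ph$plot))
    terms$plot <- tcrossprod(Zp)
    qvec <- c(qvec, ncol(Zp))
  }
  for (lab in glabels) {
    if (!lab %in% names(matrices)) stop("no relationship matrix supplied for term '", lab, "'")
    K <- matrices[[lab]]
    if (!all(ids %in% rownames(K))) stop("relationship matrix for '", lab,
                                         "' does not cover all phenotyped individuals")
    Ksub <- unclass(K)[ids, ids, drop = FALSE]
    terms[[lab]] <- bend_matrix(Ksub)
    qvec <- c(qvec, length(ids))
  }
  if (!length(terms)) stop("no random terms requested")
  structure(list(y = y, X = X, terms = terms, qvec = qvec, ids = ids,
                 trait = trait, labels = names(terms),
                 matrices = matrices[glabels]),
            class = "model_spec")
}

#' Fit a model specification by REML
#'
#' @param spec a `model_spec` from [build_model()].
#' @param ... options passed to [fit_reml()] (`algorithm`, `tolerance`,
#'   `max_iter`, `floor`).
#' @return a `reml_fit` with the spec's ids, trait and labels attached.
#' @export
fit_model <- function(spec, ...) {
  stopifnot(inherits(spec, "model_spec"))
  fit <- fit_reml(spec$y, spec$X, spec$terms, qvec = spec$qvec, ...)
  fit$ids <- spec$ids
  fit$trait <- spec$trait
  fit$labels <- spec$labels
  fit
}

#' Information criteria of a REML fit
#'
#' `AIC = -2 logL + 2 rho` with `rho` the number of estimated variance
#' parameters (fixed effects are absorbed by REML). The default BIC is the
#' standard `-2 logL + log(n) rho`; `bic_variant = "doubled"` applies a
#' doubled penalty `2 log(n) rho` used by some software reports.
#'
#' @param fit a `reml_fit`.
#' @param bic_variant `"standard"` or `"doubled"`.
#' @return named vector `c(AIC, BIC)`.
#' @export
information_criteria <- function(fit, bic_variant = c("standard", "doubled")) {
  bic_variant <- match.arg(bic_variant)
  pen <- if (bic_variant == "standard") log(fit$n) else 2 * log(fit$n)
  c(AIC = -2 * fit$logL + 2 * fit$rho, BIC = -2 * fit$logL + pen * fit$rho)
}

#' Rank fitted models by information criterion
#'
#' Models whose criterion lies within `threshold` of the best are reported as
#' tied with it.
#'
#' @param fits named list of `reml_fit` objects on the same trait and data.
#' @param criterion `"AIC"` or `"BIC"`.
#' @param threshold tie threshold (default 2).
#' @return data.frame with model, logL, AIC, BIC, delta, tied_with_best.
#' @export
compare_models <- function(fits, criterion = c("AIC", "BIC"), threshold = 2) {
  criterion <- match.arg(criterion)
  ns <- vapply(fits, function(f) f$n, numeric(1))
  trs <- vapply(fits, function(f) f$trait %||% "", character(1))
  if (length(unique(ns)) > 1 || length(unique(trs)) > 1) {
    stop("models must be fitted to the same trait and observations")
  }
  tab <- data.frame(model = names(fits),
                    logL = vapply(fits, function(f) f$logL, numeric(1)),
                    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
                    BIC = vapply(fits, function(f) f$BIC, numeric(1)),
                    converged = vapply(fits, function(f) f$converged, logical(1)),
                    stringsAsFactors = FALSE)
  tab$delta <- tab[[criterion]] - min(tab[[criterion]])
  tab$tied_with_best <- tab$delta <= threshold
  tab[order(tab[[criterion]]), , drop = FALSE]
}

#' Heritabilities and variance proportions from a fit
#'
#' Narrow-sense `h2 = sigma2_a / sigma2_P` and broad-sense
#' `H2 = sigma2_g / sigma2_P`, where `sigma2_g` sums exactly the genetic
#' components present in the model (additive, dominance, imprinting,
#' epistasis) and `sigma2_P` sums every random component including plot and
#' residual. Standard errors come from the delta method applied to the
#' inverse average-information covariance of the variance components.
#'
#' @param fit a `reml_fit` from [fit_model()].
#' @return list of class `heritability`: `h2`, `H2`, `se_h2`, `se_H2`,
#'   `sigma2_g`, `sigma2_P`, and `proportions` (per-component shares of
#'   `sigma2_P`, summing to 1).
#' @export
heritability <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  s2 <- fit$sigma2
  genetic <- intersect(c("a", "d", "i", "e"), names(s2))
  sigma2_P <- sum(s2)
  sigma2_g <- sum(s2[genetic])
  proportions <- s2 / sigma2_P
  delta_se <- function(num_idx) {
    # ratio r = sum(s2[num]) / sum(s2); grad_j = (I[j in num] * S - N) / S^2
    N <- sum(s2[num_idx]); S <- sigma2_P
    g <- (as.numeric(names(s2) %in% num_idx) * S - N) / S^2
    sqrt(max(0, as.numeric(t(g) %*% fit$vcov_sigma2 %*% g)))
  }
  if ("a" %in% names(s2)) {
    h2 <- as.numeric(s2["a"] / sigma2_P)
    se_h2 <- delta_se("a")
  } else {
    h2 <- NA_real_; se_h2 <- NA_real_
  }
  H2 <- sigma2_g / sigma2_P
  se_H2 <- delta_se(genetic)
  structure(list(h2 = h2, H2 = H2, se_h2 = se_h2, se_H2 = se_H2,
                 sigma2_g = sigma2_g, sigma2_P = sigma2_P,
                 proportions = proportions),
            class = "heritability")
}

#' @export
print.heritability <- function(x, ...) {
  cat(sprintf("h2 = %.3f (SE %.3f), H2 = %.3f (SE %.3f)\n",
              x$h2, x$se_h2, x$H2, x$se_H2))
  print(round(x$proportions, 4))
  invisible(x)
}

#' Extract genetic-value BLUPs from a fit
#'
#' @param fit a `reml_fit` from [fit_model()].
#' @param which `"additive_only"` (the breeding values) or `"total_genetic"`
#'   (sum of all fitted genetic-term BLUPs).
#' @return named numeric vector aligned to individual ids.
#' @export
extract_blups <- function(fit, which = c("additive_only", "total_genetic")) {
  which <- match.arg(which)
  genetic <- intersect(c("a", "d", "i", "e"), names(fit$blup))
  if (which == "additive_only") {
    if (!"a" %in% genetic) stop("fit has no additive term")
    out <- fit$blup[["a"]]
  } else {
    if (!length(genetic)) stop("fit has no genetic terms")
    out <- Reduce(`+`, fit$blup[genetic])
  }
  stats::setNames(out, fit$ids)
}

#' Predict genetic values for individuals outside the fit
#'
#' BLUP prediction through the relationship-matrix covariances linking new
#' individuals to the training individuals:
#' `u_new = sigma2_k K[new, train] P y` per genetic term.
#'
#' @param fit a `reml_fit` from [fit_model()] (its `model_spec` must have
#'   been built from matrices covering the new individuals).
#' @param matrices named list of full `rel_matrix` objects (covering training
#'   and new ids) for the fit's genetic labels.
#' @param new_ids character ids to predict.
#' @param which `"additive_only"` or `"total_genetic"`.
#' @return named numeric vector of predicted genetic values.
#' @export
predict_genetic <- function(fit, matrices, new_ids,
                            which = c("additive_only", "total_genetic")) {
  which <- match.arg(which)
  genetic <- intersect(c("a", "d", "i", "e"), names(fit$blup))
  labs <- if (which == "additive_only") "a" else genetic
  if (!length(labs) || (which == "additive_only" && !"a" %in% genetic)) {
    stop("fit lacks the requested genetic terms")
  }
  out <- stats::setNames(numeric(length(new_ids)), new_ids)
  for (lab in labs) {
    K <- unclass(matrices[[lab]])
    if (!all(new_ids %in% rownames(K))) stop("matrix for '", lab, "' does not cover the new ids")
    out <- out + fit$sigma2[lab] * as.vector(K[new_ids, fit$ids, drop = FALSE] %*% fit$Py)
  }
  out
}
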