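#' Block-adjusted phenotypes
#'
#' Ordinary least-squares fit of the trait on the block factor over all
#' phenotyped individuals; the adjusted phenotype is the residual
#' `y - (intercept + block effect)`. With a single block this reduces to
#' centering.
#'
#' @param pheno data.frame with `id`, the trait and `block`.
#' @param trait trait column name.
#' @return named numeric vector (ids of phenotyped individuals).
#' @export
adjust_phenotypes <- function(pheno, trait) {
  keep <- !is.na(pheno[[trait]])
  ph <- pheno[keep, , drop = FALSE]
  y <- ph[[trait]]
  if (length(unique(ph$block)) < 2) {
    return(stats::setNames(y - mean(y), ph$id))
  }
  fit <- stats::lm(y ~ factor(ph$block))
  stats::setNames(as.numeric(stats::residuals(fit)), ph$id)
}

#' Replicated k-fold cross-validation plans
#'
#' Per replicate, a fresh seeded shuffle partitions the ids into `k` folds
#' whose sizes differ by at most one; plans are reproducible bit-for-bit
#' under a fixed seed.
#'
#' @param ids character vector of individuals.
#' @param k folds per replicate (default 10).
#' @param replicates number of replicates (default 10).
#' @param seed integer seed.
#' @return data.frame of class `fold_plan` with columns `replicate`, `fold`,
#'   `id` (validation membership).
#' @export
make_folds <- function(ids, k = 10L, replicates = 10L, seed = 1L) {
  if (k > length(ids)) stop("more folds than individuals")
  plans <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    set.seed(draw_seed(seed, r))
    shuffled <- sample(ids)
    # contiguous blocks over the shuffle give fold sizes differing by <= 1
    fold <- sort(rep_len(seq_len(k), length(ids)))
    plans[[r]] <- data.frame(replicate = r, fold = fold, id = shuffled,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, plans)
  class(out) <- c("fold_plan", "data.frame")
  out
}

#' Predictive ability of a set of predictions
#'
#' Pearson correlation between predicted genetic values and block-adjusted
#' phenotypes, restricted to the validation individuals with both values
#' present. Returns `NA` (with a warning) when fewer than 3 pairs overlap or
#' either side has zero variance.
#'
#' @param predicted named numeric vector of predictions.
#' @param adjusted named numeric vector of block-adjusted phenotypes.
#' @param validation character ids of the validation set.
#' @return correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
predictive_ability <- function(predicted, adjusted, validation) {
  ids <- intersect(validation, intersect(names(predicted), names(adjusted)))
  p <- predicted[ids]; a <- adjusted[ids]
  ok <- !is.na(p) & !is.na(a)
  if (sum(ok) < 3 || stats::sd(p[ok]) == 0 || stats::sd(a[ok]) == 0) {
    warning("predictive ability undefined (fewer than 3 pairs or zero variance)")
    return(NA_real_)
  }
  stats::cor(p[ok], a[ok])
}

#' Drop genetic terms with negligible variance contribution
#'
#' Genetic terms whose variance proportion falls below the threshold are
#' dropped from the model; the additive term is always retained.
#'
#' @param fit a `reml_fit` of the full model.
#' @param negligible_threshold proportion below which a term is dropped
#'   (default 0.05).
#' @return character vector of retained genetic labels.
#' @export
select_optimal_terms <- function(fit, negligible_threshold = 0.05) {
  h <- heritability(fit)
  genetic <- intersect(c("a", "d", "i", "e"), names(h$proportions))
  keep <- genetic[h$proportions[genetic] >= negligible_threshold]
  union("a", keep)
}

#' Run cross-validated genomic prediction
#'
#' For each (replicate, fold): fits the model to the training individuals
#' only (validation phenotypes are excluded from the REML fits and masked to
#' `NA` in the Gibbs fits), predicts validation genetic values, and scores
#' the Pearson correlation with block-adjusted phenotypes. The prediction
#' target is the additive BLUP for the benchmark additive model and the
#' total genetic value for multi-component models.
#'
#' @param pheno phenotype data.frame (`id`, trait, `block`, `plot`).
#' @param trait trait column name.
#' @param folds a `fold_plan` from [make_folds()].
#' @param method `"gblup"` (REML) or `"rkhs"` (Gibbs).
#' @param matrices named list of `rel_matrix` objects over all individuals
#'   (`a`, `d`, `i`, `e` as needed) for `method = "gblup"`.
#' @param kernels named list of kernels over all individuals for
#'   `method = "rkhs"`.
#' @param include genetic labels of the model (default `"a"`, the benchmark).
#' @param target `"additive_only"` or `"total_genetic"`; default additive for
#'   the single-term benchmark, total genetic otherwise.
#' @param gibbs a [gibbs_config()] for `method = "rkhs"`.
#' @param label model label stored in the result.
#' @param ... further options to [fit_model()].
#' @return data.frame of class `cv_result`: `replicate`, `fold`, `n_val`,
#'   `pa`, plus attributes `label` and `trait`.
#' @export
run_cv <- function(pheno, trait, folds, method = c("gblup", "rkhs"),
                   matrices = NULL, kernels = NULL, include = "a",
                   target = NULL, gibbs = gibbs_config(), label = NULL, ...) {
  method <- match.arg(method)
  target <- target %||% (if (identical(setdiff(include, "plot"), "a"))
    "additive_only" else "total_genetic")
  adjusted <- adjust_phenotypes(pheno, trait)
  phen_ids <- names(adjusted)
  res <- list()
  for (r in sort(unique(folds$replicate))) {
    for (f in sort(unique(folds$fold[folds$replicate == r]))) {
      val <- intersect(folds$id[folds$replicate == r & folds$fold == f], phen_ids)
      train <- setdiff(phen_ids, val)
      pa <- tryCatch({
        if (method == "gblup") {
          ph_train <- pheno[pheno$id %in% train, , drop = FALSE]
          spec <- build_model(ph_train, trait, matrices, include = include)
          fit <- fit_model(spec, ...)
          pred <- predict_genetic(fit, matrices, val, which = target)
        } else {
          ord <- rownames(unclass(kernels[[1]]))
          ph <- pheno[match(ord, pheno$id), , drop = FALSE]
          yv <- ph[[trait]]
          yv[ph$id %in% val] <- NA
          blocks <- factor(ph$block)
          X <- stats::model.matrix(~blocks)
          cfg <- gibbs
          cfg$seed <- draw_seed(gibbs$seed, r * 100L + f)
          fit <- fit_gibbs(yv, X, kernels, config = cfg)
          pred <- posterior_genetic_values(fit, which = target)[val]
        }
        predictive_ability(pred, adjusted, val)
      }, error = function(e) {
        warning(sprintf("fold (%d, %d) skipped: %s", r, f, conditionMessage(e)))
        NA_real_
      })
      res[[length(res) + 1L]] <- data.frame(replicate = r, fold = f,
                                            n_val = length(val), pa = pa)
    }
  }
  out <- do.call(rbind, res)
  attr(out, "label") <- label %||% method
  attr(out, "trait") <- trait
  class(out) <- c("cv_result", "data.frame")
  out
}

#' Summarise a cross-validation result
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @return data.frame with fold-level and replicate-level mean/median PA.
#' @export
summary.cv_result <- function(object, ...) {
  pa <- object$pa[!is.na(object$pa)]
  per_rep <- tapply(object$pa, object$replicate, mean, na.rm = TRUE)
  data.frame(label = attr(object, "label") %||% "", trait = attr(object, "trait") %||% "",
             n_scores = length(pa), mean_pa = mean(pa), median_pa = stats::median(pa),
             mean_of_replicate_means = mean(per_rep, na.rm = TRUE))
}

#' Paired comparison of two cross-validation results
#'
#' Paired two-sided t-test on fold-level predictive abilities matched by
#' (replicate, fold), with a Wilcoxon signed-rank companion. Stars follow the
#' usual convention: `**` at p < 0.01, `*` at p < 0.05, `ns` otherwise.
#' Zero-variance differences are handled by their sign (identical results
#' give p = 1; a constant non-zero shift is reported as significant).
#'
#' @param a,b `cv_result` objects on identical fold plans.
#' @return list with `mean_diff` (a - b), `t_p`, `wilcoxon_p`, `stars`, `n`.
#' @export
compare_pa <- function(a, b) {
  key_a <- paste(a$replicate, a$fold)
  key_b <- paste(b$replicate, b$fold)
  if (!identical(sort(key_a), sort(key_b))) stop("fold plans do not match")
  d <- a$pa[order(key_a)] - b$pa[order(key_b)]
  d <- d[!is.na(d)]
  if (length(d) < 2) stop("fewer than 2 paired scores")
  if (stats::sd(d) < 1e-12 * max(abs(d), 1)) {
    t_p <- if (abs(mean(d)) < 1e-12) 1 else 0
    w_p <- t_p
  } else {
    t_p <- stats::t.test(d)$p.value
    w_p <- suppressWarnings(stats::wilcox.test(d)$p.value)
  }
  stars <- if (t_p < 0.01) "**" else if (t_p < 0.05) "*" else "ns"
  list(mean_diff = mean(d), t_p = t_p, wilcoxon_p = w_p, stars = stars,
       n = length(d))
}

#' Box plot of predictive abilities across models
#'
#' @param results list of `cv_result` objects.
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_cv <- function(results) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_cv needs the ggplot2 package")
  }
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(model = attr(r, "label"), pa = r$pa)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = model, y = pa)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 16) +
    ggplot2::labs(x = NULL, y = "Predictive ability")
}
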