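#' Gaussian reproducing kernel from marker rows
#'
#' `K_xy = exp(-h * d2_xy)` where `d2_xy` is the squared Euclidean distance
#' between the marker rows of x and y, normalized by its average over all
#' pairs so the bandwidth `h` is scale-free. The kernel has unit diagonal and
#' entries in (0, 1]; as `h -> 0` it tends to the all-ones matrix.
#'
#' @param M numeric matrix with one row per individual (e.g. a marker
#'   matrix); rownames are the individual ids.
#' @param h bandwidth, > 0.
#' @return a `rel_matrix` of kind `kernel` with attribute `h`.
#' @export
build_kernel <- function(M, h = 1) {
  if (h <= 0) stop("bandwidth h must be > 0")
  if (is.null(rownames(M))) stop("marker matrix needs individual ids as rownames")
  D2 <- as.matrix(stats::dist(M))^2
  off <- D2[upper.tri(D2)]
  norm <- mean(off)
  if (!is.finite(norm) || norm <= 0) norm <- 1
  K <- exp(-h * D2 / norm)
  out <- rel_matrix(K, "kernel")
  attr(out, "h") <- h
  out
}

#' Kernel set for the RKHS genetic components
#'
#' Builds Gaussian kernels from the additive, dominance and imprinting
#' marker matrices and, by default, the Hadamard square of the additive
#' kernel for the epistatic component. With several bandwidths per component
#' (the default `h = c(0.25, 1, 5)`), kernel averaging is used: each
#' (component, bandwidth) pair becomes its own random term. With
#' `include_linear = TRUE` (the default) the averaging set additionally
#' contains each component's linear kernel — the genomic relationship matrix
#' itself (and its Hadamard square for the epistatic component) — so the
#' RKHS model space nests the corresponding GBLUP model.
#'
#' @param G complete, phased `geno_matrix` (imputed/filtered); see
#'   [genomic_matrices()].
#' @param components subset of `c("a", "d", "i", "e")`.
#' @param h Gaussian bandwidth(s); a single value with
#'   `include_linear = FALSE` disables kernel averaging.
#' @param include_linear add the linear (relationship-matrix) kernel of each
#'   component to the averaging set.
#' @param pedigree optional pedigree for [resolve_phase()] when the
#'   imprinting component is requested.
#' @param epistasis_kernel `"hadamard"` (default, `K_E = K_A # K_A`) or
#'   `"gaussian"` (its own Gaussian kernel on the additive marker rows).
#' @return named list of `rel_matrix` kernels named `<component>_h<h>` /
#'   `<component>_lin` (or bare `a`, `d`, ... when a single kernel per
#'   component is requested).
#' @export
kernel_set <- function(G, components = c("a", "e"), h = c(0.25, 1, 5),
                       include_linear = TRUE, pedigree = NULL,
                       epistasis_kernel = c("hadamard", "gaussian")) {
  epistasis_kernel <- match.arg(epistasis_kernel)
  Gm <- orient_minor(G)
  if ("i" %in% components && !is.null(pedigree)) Gm <- resolve_phase(Gm, pedigree)
  base <- list()
  if (any(c("a", "e") %in% components)) base$a <- marker_matrix_additive(Gm)
  if ("d" %in% components) base$d <- marker_matrix_dominance(Gm)
  if ("i" %in% components) base$i <- marker_matrix_imprinting(Gm)
  multi <- length(h) > 1 || include_linear
  tag <- function(comp, suffix) if (multi) sprintf("%s_%s", comp, suffix) else comp
  kernels <- list()
  if (include_linear) {
    GA <- if (any(c("a", "e") %in% components)) {
      rel_matrix(bend_matrix(unclass(genomic_matrix(base$a, "A"))), "kernel")
    } else NULL
    if ("a" %in% components) kernels[[tag("a", "lin")]] <- GA
    if ("d" %in% components) {
      kernels[[tag("d", "lin")]] <- rel_matrix(bend_matrix(unclass(genomic_matrix(base$d, "D"))), "kernel")
    }
    if ("i" %in% components) {
      kernels[[tag("i", "lin")]] <- rel_matrix(bend_matrix(unclass(genomic_matrix(base$i, "I"))), "kernel")
    }
    if ("e" %in% components) {
      kernels[[tag("e", "lin")]] <- rel_matrix(bend_matrix(unclass(GA) * unclass(GA)), "kernel")
    }
  }
  for (hh in h) {
    KA <- if (any(c("a", "e") %in% components)) build_kernel(base$a, hh) else NULL
    if ("a" %in% components) kernels[[tag("a", paste0("h", hh))]] <- KA
    if ("d" %in% components) kernels[[tag("d", paste0("h", hh))]] <- build_kernel(base$d, hh)
    if ("i" %in% components) kernels[[tag("i", paste0("h", hh))]] <- build_kernel(base$i, hh)
    if ("e" %in% components) {
      KE <- if (epistasis_kernel == "hadamard") {
        rel_matrix(unclass(KA) * unclass(KA), "kernel")
      } else build_kernel(base$a, hh)
      kernels[[tag("e", paste0("h", hh))]] <- KE
    }
  }
  kernels
}

#' Gibbs-sampler settings for RKHS fits
#'
#' Defaults follow common practice for kernel regression on data of this
#' size: 20,000 iterations, 2,000 burn-in, thinning 100 (180 retained
#' draws). Variance priors are scaled inverse chi-square with `prior_df`
#' degrees of freedom; each prior scale is set so that the prior mode equals
#' an equal split of the phenotypic variance across all variance terms.
#'
#' @param n_iter,burn_in,thin chain settings.
#' @param prior_df prior degrees of freedom for every variance component.
#' @param seed integer seed.
#' @return list of class `gibbs_config`.
#' @export
gibbs_config <- function(n_iter = 20000L, burn_in = 2000L, thin = 100L,
                         prior_df = 5, seed = 1L) {
  kept <- (n_iter - burn_in) / thin
  if (kept < 50) stop("chain settings retain fewer than 50 draws")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), prior_df = prior_df,
                 seed = as.integer(seed)), class = "gibbs_config")
}

#' Fit an RKHS regression by Gibbs sampling
#'
#' Bayesian linear mixed model `y = X beta + sum_k u_k + eps` with
#' `u_k ~ N(0, sigma2_k K_k)` for PSD kernels `K_k`, flat prior on `beta`,
#' and scaled inverse chi-square priors on all variances. Each `u_k` is
#' sampled in the eigenbasis of its kernel, where the conditional posterior
#' is diagonal. Missing responses (e.g. masked validation trees) are imputed
#' from their conditional normal each sweep, so they carry no information
#' about the parameters; their genetic values are predicted through the
#' kernel covariances with the observed individuals.
#'
#' @param y response vector, `NA` for individuals to predict.
#' @param X fixed-effect design matrix.
#' @param kernels named list of `rel_matrix` kernels (or any PSD covariance
#'   matrices) over all individuals, in the order of `y`.
#' @param config a [gibbs_config()].
#' @param eig_tol eigenvalues below `eig_tol * max(eigenvalue)` are dropped.
#' @return object of class `gibbs_fit`: `draws` (matrix of retained variance
#'   and fixed-effect draws), posterior mean genetic values per component
#'   (`u_mean`), `ess` per variance component, and the config.
#' @export
fit_gibbs <- function(y, X, kernels, config = gibbs_config(), eig_tol = 1e-8) {
  stopifnot(inherits(config, "gibbs_config"))
  n <- length(y)
  k <- length(kernels)
  ids <- if (k > 0) rownames(unclass(kernels[[1]])) %||% as.character(seq_len(n))
         else names(y) %||% as.character(seq_len(n))
  obs <- !is.na(y)
  set.seed(config$seed)
  eig <- lapply(kernels, function(K) {
    e <- eigen(unclass(K), symmetric = TRUE)
    keep <- e$values > eig_tol * max(e$values)
    list(U = e$vectors[, keep, drop = FALSE], d = e$values[keep])
  })
  XtX <- crossprod(X)
  XtX_inv <- solve(XtX)
  chB <- chol(XtX_inv)
  nu <- config$prior_df
  vy <- stats::var(y[obs])
  S0 <- vy / (k + 1) * (nu + 2) / nu  # prior mode at an equal variance split

  beta <- rep(0, ncol(X)); beta[1] <- mean(y[obs])
  yy <- y; yy[!obs] <- mean(y[obs])
  alpha <- lapply(eig, function(e) rep(0, length(e$d)))
  u <- lapply(eig, function(e) rep(0, n))
  sigma2 <- rep(vy / (k + 1), k + 1L)

  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  comp_names <- if (k > 0) names(kernels) %||% paste0("K", seq_len(k)) else character(0)
  draws <- matrix(NA_real_, n_keep,
                  k + 1L + ncol(X),
                  dimnames = list(NULL, c(comp_names, "residual", colnames(X))))
  u_sum <- lapply(seq_len(k), function(j) rep(0, n))
  kept <- 0L
  for (it in seq_len(config$n_iter)) {
    utot <- if (k > 0) Reduce(`+`, u) else rep(0, n)
    # impute masked responses from their conditional normal
    if (any(!obs)) {
      mu_mis <- (X %*% beta)[!obs] + utot[!obs]
      yy[!obs] <- stats::rnorm(sum(!obs), mu_mis, sqrt(sigma2[k + 1L]))
    }
    # fixed effects
    r <- yy - utot
    bhat <- XtX_inv %*% crossprod(X, r)
    beta <- as.vector(bhat + sqrt(sigma2[k + 1L]) * crossprod(chB, stats::rnorm(ncol(X))))
    resid <- yy - as.vector(X %*% beta) - utot
    # each component in its eigenbasis (diagonal conditional)
    for (j in seq_len(k)) {
      resid <- resid + u[[j]]
      v <- crossprod(eig[[j]]$U, resid)
      prec <- 1 / sigma2[k + 1L] + 1 / (sigma2[j] * eig[[j]]$d)
      mu <- (v / sigma2[k + 1L]) / prec
      alpha[[j]] <- as.vector(mu + stats::rnorm(length(mu)) / sqrt(prec))
      u[[j]] <- as.vector(eig[[j]]$U %*% alpha[[j]])
      resid <- resid - u[[j]]
      ssq <- sum(alpha[[j]]^2 / eig[[j]]$d)
      sigma2[j] <- (ssq + nu * S0) / stats::rchisq(1, nu + length(alpha[[j]]))
    }
    sigma2[k + 1L] <- (sum(resid^2) + nu * S0) / stats::rchisq(1, nu + n)
    if (!all(is.finite(sigma2))) stop("divergent chain at iteration ", it)
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- c(sigma2, beta)
      for (j in seq_len(k)) u_sum[[j]] <- u_sum[[j]] + u[[j]]
    }
  }
  u_mean <- lapply(u_sum, function(s) stats::setNames(s / kept, ids))
  names(u_mean) <- comp_names
  ess <- apply(draws[, seq_len(k + 1L), drop = FALSE], 2, ess_basic)
  structure(list(draws = draws, u_mean = u_mean, ids = ids, obs = obs,
                 ess = ess, config = config,
                 posterior_mean = colMeans(draws),
                 posterior_sd = apply(draws, 2, stats::sd)),
            class = "gibbs_fit")
}

ess_basic <- function(x) {
  m <- length(x)
  if (stats::sd(x) == 0) return(m)
  ac <- stats::acf(x, lag.max = min(m - 1L, 40L), plot = FALSE)$acf[-1]
  pos <- ac[seq_len(max(1, which(ac < 0)[1] - 1, na.rm = TRUE))]
  pos <- pos[!is.na(pos) & pos > 0]
  m / (1 + 2 * sum(pos))
}

#' Posterior-mean genetic values from a Gibbs fit
#'
#' Sums the posterior means of the requested components. With kernel
#' averaging the bandwidth-specific terms of one component are summed, so
#' `additive_only` returns all `a_h*` terms and `total_genetic` everything.
#'
#' @param fit a `gibbs_fit`.
#' @param which `"additive_only"` or `"total_genetic"`.
#' @return named numeric vector over all individuals in the kernels
#'   (including any with masked response, whose values are predictions).
#' @export
posterior_genetic_values <- function(fit, which = c("additive_only", "total_genetic")) {
  which <- match.arg(which)
  labs <- names(fit$u_mean)
  if (which == "additive_only") {
    labs <- labs[labs == "a" | startsWith(labs, "a_")]
    if (!length(labs)) stop("fit has no additive kernel term")
  }
  Reduce(`+`, fit$u_mean[labs])
}

#' @export
print.gibbs_fit <- function(x, ...) {
  k <- length(x$u_mean)
  cat(sprintf("RKHS Gibbs fit: %d retained draws, %d kernel terms\n",
              nrow(x$draws), k))
  print(round(x$posterior_mean[seq_len(k + 1L)], 4))
  invisible(x)
}
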