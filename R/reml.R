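# Generic multi-kernel linear mixed model, y = X beta + sum_k u_k + eps with
# u_k ~ N(0, sigma2_k V_k) and eps ~ N(0, sigma2_e I), fitted by restricted
# maximum likelihood. The engine works on the variance scale with
# average-information (AI) quasi-Newton updates, step-halving when a step
# would decrease the restricted log-likelihood, projection onto the positive
# constraint floor, and the classical EM update as a monotone fallback.

reml_objective <- function(y, X, Vlist, sigma2) {
  n <- length(y)
  k <- length(Vlist)
  V <- diag(sigma2[k + 1L], n)
  for (j in seq_len(k)) V <- V + sigma2[j] * Vlist[[j]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logdetV <- 2 * sum(log(diag(ch)))
  Vinv <- chol2inv(ch)
  VX <- Vinv %*% X
  XtVX <- crossprod(X, VX)
  chX <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(chX)) return(NULL)
  logdetX <- 2 * sum(log(diag(chX)))
  Cinv <- chol2inv(chX)
  P <- Vinv - VX %*% Cinv %*% t(VX)
  Py <- as.vector(P %*% y)
  logL <- -0.5 * (logdetV + logdetX + sum(y * Py))
  list(logL = logL, P = P, Py = Py, Vinv = Vinv, Cinv = Cinv, VX = VX)
}

reml_derivatives <- function(y, Vlist, st) {
  k <- length(Vlist)
  n <- length(y)
  w <- vector("list", k + 1L)       # V_k P y
  trPV <- numeric(k + 1L)
  yPVPy <- numeric(k + 1L)
  for (j in seq_len(k)) {
    w[[j]] <- as.vector(Vlist[[j]] %*% st$Py)
    trPV[j] <- sum(st$P * Vlist[[j]])
    yPVPy[j] <- sum(st$Py * w[[j]])
  }
  w[[k + 1L]] <- st$Py
  trPV[k + 1L] <- sum(diag(st$P))
  yPVPy[k + 1L] <- sum(st$Py^2)
  W <- do.call(cbind, w)
  PW <- st$P %*% W
  AI <- 0.5 * crossprod(W, PW)
  score <- -0.5 * (trPV - yPVPy)
  list(score = score, AI = AI, trPV = trPV, yPVPy = yPVPy)
}

#' Fit a multi-kernel linear mixed model by REML
#'
#' Maximizes the restricted likelihood of
#' `y = X beta + sum_k u_k + eps`, `u_k ~ N(0, sigma2_k V_k)`,
#' `eps ~ N(0, sigma2_res I)`, over positively constrained variance
#' components. The default algorithm takes one EM warm-up step, then
#' average-information updates with step-halving; components pushed below the
#' floor are held there (still counted among the estimated parameters) and
#' may re-enter if their score turns positive. `algorithm = "EM"` uses pure
#' EM updates, which never decrease the restricted log-likelihood.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (full column rank).
#' @param Vlist named list of n x n covariance structures, one per random
#'   term (the residual identity term is implicit).
#' @param qvec number of levels of each random term, used by the EM update
#'   (defaults to `n` for each term; pass the number of plots for a plot
#'   term).
#' @param algorithm `"AI"` (AI with EM fallback) or `"EM"`.
#' @param tolerance convergence threshold on the largest relative change of
#'   any variance component.
#' @param max_iter iteration cap; non-convergence gives a usable fit flagged
#'   `converged = FALSE`.
#' @param floor lower constraint for every variance component; default
#'   `1e-8 * var(y)`, small enough that holding a component at the floor is
#'   numerically indistinguishable from omitting it.
#' @param start optional starting values (length `length(Vlist) + 1`).
#' @return object of class `reml_fit`: variance components `sigma2` (last
#'   element residual), `beta`, `blup` (list per term), `Py`, restricted
#'   `logL`, `AIC`/`BIC`, `vcov_sigma2` (inverse AI over free components),
#'   `n`, `rho`, convergence diagnostics.
#' @export
fit_reml <- function(y, X, Vlist, qvec = NULL,
                     algorithm = c("AI", "EM"),
                     tolerance = 1e-8, max_iter = 200L,
                     floor = NULL, start = NULL) {
  algorithm <- match.arg(algorithm)
  stopifnot(is.numeric(y), nrow(X) == length(y))
  k <- length(Vlist)
  n <- length(y)
  if (n <= ncol(X)) stop("need more observations than fixed effects")
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design matrix")
  if (is.null(qvec)) qvec <- rep(n, k)
  floor <- floor %||% (1e-8 * stats::var(y))
  sigma2 <- start %||% rep(stats::var(y) / (k + 1L), k + 1L)
  sigma2 <- pmax(sigma2, floor)
  qv <- c(qvec, n)

  st <- reml_objective(y, X, Vlist, sigma2)
  if (is.null(st)) stop("initial covariance matrix not positive definite")
  em_step <- function(sigma2, st, dv) {
    pmax(sigma2 + sigma2^2 / qv * (dv$yPVPy - dv$trPV), floor)
  }
  converged <- FALSE
  iter <- 0L
  dv <- reml_derivatives(y, Vlist, st)
  logL_path <- st$logL
  repeat {
    iter <- iter + 1L
    if (iter == 1L || algorithm == "EM") {
      cand <- em_step(sigma2, st, dv)
    } else {
      free <- !(sigma2 <= floor * (1 + 1e-8) & dv$score < 0)
      if (!any(free)) {
        cand <- sigma2
      } else {
        AIf <- dv$AI[free, free, drop = FALSE]
        delta <- tryCatch(solve(AIf + diag(1e-10 * mean(diag(AIf)), sum(free)),
                                dv$score[free]),
                          error = function(e) NULL)
        if (is.null(delta)) {
          cand <- em_step(sigma2, st, dv)
        } else {
          cand <- sigma2
          cand[free] <- cand[free] + delta
          cand <- pmax(cand, floor)
          # step-halving on the restricted likelihood
          h <- 0L
          repeat {
            st_c <- reml_objective(y, X, Vlist, cand)
            if (!is.null(st_c) && st_c$logL >= st$logL - 1e-10) break
            h <- h + 1L
            if (h > 20L) { cand <- em_step(sigma2, st, dv); break }
            delta <- delta / 2
            cand <- sigma2
            cand[free] <- cand[free] + delta
            cand <- pmax(cand, floor)
          }
        }
      }
    }
    st_new <- reml_objective(y, X, Vlist, cand)
    if (is.null(st_new)) { cand <- em_step(sigma2, st, dv); st_new <- reml_objective(y, X, Vlist, cand) }
    rel <- max(abs(cand - sigma2) / pmax(abs(sigma2), floor))
    sigma2 <- cand
    st <- st_new
    dv <- reml_derivatives(y, Vlist, st)
    logL_path <- c(logL_path, st$logL)
    if (rel < tolerance) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  beta <- as.vector(st$Cinv %*% crossprod(st$VX, y))
  names(beta) <- colnames(X)
  blup <- vector("list", k)
  names(blup) <- names(Vlist)
  for (j in seq_len(k)) blup[[j]] <- sigma2[j] * as.vector(Vlist[[j]] %*% st$Py)
  rho <- k + 1L
  logL <- st$logL
  free <- !(sigma2 <= floor * (1 + 1e-8))
  vcov_sigma2 <- matrix(0, k + 1L, k + 1L)
  if (any(free)) {
    vc <- tryCatch(solve(dv$AI[free, free, drop = FALSE]), error = function(e) NULL)
    if (!is.null(vc)) vcov_sigma2[free, free] <- vc
  }
  term_names <- if (k > 0) names(Vlist) %||% paste0("V", seq_len(k)) else character(0)
  comp_names <- c(term_names, "residual")
  names(sigma2) <- comp_names
  dimnames(vcov_sigma2) <- list(comp_names, comp_names)
  structure(list(sigma2 = sigma2, beta = beta, blup = blup, Py = st$Py,
                 logL = logL, AIC = -2 * logL + 2 * rho,
                 BIC = -2 * logL + log(n) * rho,
                 rho = rho, n = n, floor = floor,
                 vcov_sigma2 = vcov_sigma2,
                 converged = converged, iterations = iter,
                 logL_path = logL_path,
                 algorithm = algorithm, score = dv$score),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("REML fit (%s): n = %d, logL = %.4f%s\n", x$algorithm, x$n, x$logL,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(x$sigma2, 6))
  invisible(x)
}
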