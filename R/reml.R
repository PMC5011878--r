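#' REML fit of a one-random-factor model with stratified residual variance
#'
#' Fits `y = X beta + Z u + e` where `Z` is the indicator matrix of a single
#' grouping factor (`u ~ N(0, sigma2_u I)`) and the residual variance may
#' differ between strata (`e_i ~ N(0, sigma2_e[stratum_i])`). This covers
#' every model in the split-nitrogen analysis: the genotype-replication
#' interaction as the random term with per-nitrogen-level residual variances,
#' the random-genotype model used for heritability, and (with `group = NULL`)
#' plain generalized/ordinary least squares.
#'
#' Variance components are profiled out of the restricted likelihood and
#' optimized on the log scale, which enforces non-negativity; estimates
#' driven to the boundary are reported as 0. Because the covariance matrix is
#' block-diagonal in the grouping factor, each likelihood evaluation uses the
#' rank-one Woodbury identity per group and is linear in the number of
#' observations.
#'
#' @param y numeric response.
#' @param X fixed-effects design matrix (full column rank after dropping
#'   aliased columns, which are removed with a message in `$aliased`).
#' @param group factor defining the random intercepts, or `NULL` for none.
#' @param stratum factor defining residual-variance strata, or `NULL` for a
#'   single residual variance.
#' @param tol relative convergence tolerance on -2 log restricted likelihood.
#' @return List with `beta` (named), `vcov_beta`, `sigma2_u`, `sigma2_e`
#'   (named by stratum), `blup` (named by group level), `logLik_reml`,
#'   `fitted`, `residuals`, `converged`, `aliased`, `n`, `p`.
#' @export
reml_fit <- function(y, X, group = NULL, stratum = NULL, tol = 1e-10) {
  y <- as.numeric(y)
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  # drop aliased columns
  qrX <- qr(X)
  aliased <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    aliased <- colnames(X)[-keep]
    X <- X[, sort(keep), drop = FALSE]
  }
  p <- ncol(X)
  if (n <= p) stop("not enough observations to estimate residual variance",
                   call. = FALSE)

  has_u <- !is.null(group)
  if (has_u) group <- droplevels(as.factor(group))
  strat <- if (is.null(stratum)) factor(rep("all", n)) else droplevels(as.factor(stratum))
  ns <- nlevels(strat)
  sidx <- as.integer(strat)

  # zero-noise short-circuit: response exactly on the fixed-effect surface
  ols <- qr.solve(X, y)
  rss <- sum((y - X %*% ols)^2)
  scale_y <- sum(y^2) + 1
  if (rss < 1e-20 * scale_y) {
    beta <- drop(ols); names(beta) <- colnames(X)
    s2e <- rep(0, ns); names(s2e) <- levels(strat)
    blup <- if (has_u) stats::setNames(rep(0, nlevels(group)), levels(group)) else NULL
    return(list(beta = beta, vcov_beta = matrix(0, p, p, dimnames = list(colnames(X), colnames(X))),
                sigma2_u = if (has_u) 0 else NULL, sigma2_e = s2e, blup = blup,
                logLik_reml = Inf, fitted = drop(X %*% ols), residuals = y - drop(X %*% ols),
                converged = TRUE, aliased = aliased, n = n, p = p))
  }
  s2_init <- rss / (n - p)

  # -2 restricted log-likelihood (up to an additive constant) at log-variances th
  neg2relik <- function(th) {
    if (has_u) { s2u <- exp(th[1]); s2e <- exp(th[-1]) } else { s2u <- 0; s2e <- exp(th) }
    d <- s2e[sidx]
    wy <- y / d
    wX <- X / d
    if (has_u) {
      sg <- rowsum(1 / d, group)                    # per-group sum of 1/d
      cg <- drop(s2u / (1 + s2u * sg))              # Woodbury factor per group
      A <- rowsum(wX, group)                        # G x p
      ay <- rowsum(wy, group)                       # G x 1
      XtViX <- crossprod(wX, X) - crossprod(A * sqrt(cg))
      XtViy <- crossprod(wX, y) - crossprod(A, cg * ay)
      ytViy <- sum(y * wy) - sum(cg * ay^2)
      logdetV <- sum(log(d)) + sum(log1p(s2u * sg))
    } else {
      XtViX <- crossprod(wX, X)
      XtViy <- crossprod(wX, y)
      ytViy <- sum(y * wy)
      logdetV <- sum(log(d))
    }
    ch <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    b <- backsolve(ch, forwardsolve(t(ch), XtViy))
    ytPy <- ytViy - sum(XtViy * b)
    if (!is.finite(ytPy) || ytPy < 0) return(1e10)
    val <- logdetV + 2 * sum(log(diag(ch))) + ytPy
    if (!is.finite(val)) 1e10 else val
  }

  # no random term, single stratum: REML has the closed form RSS / (n - p)
  if (!has_u && ns == 1L) {
    s2e <- stats::setNames(s2_init, levels(strat))
    XtX <- crossprod(X) / s2_init
    C <- solve(XtX)
    beta <- drop(qr.solve(X, y))
    fitted <- drop(X %*% beta)
    dimnames(C) <- list(colnames(X), colnames(X))
    return(list(beta = stats::setNames(beta, colnames(X)), vcov_beta = C,
                sigma2_u = NULL, sigma2_e = s2e, blup = NULL,
                logLik_reml = -0.5 * (sum(log(rep(s2_init, n))) +
                                        determinant(XtX)$modulus[1] +
                                        (n - p) + (n - p) * log(2 * pi)),
                fitted = fitted, residuals = y - fitted,
                converged = TRUE, aliased = aliased, n = n, p = p))
  }

  th0 <- log(rep(s2_init, ns + has_u))
  if (has_u) th0[1] <- log(s2_init / 2 + 1e-12)
  if (length(th0) == 1L) {
    opt <- stats::optim(th0, neg2relik, method = "Brent",
                        lower = log(s2_init) - 35, upper = log(s2_init) + 35,
                        control = list(reltol = 1e-15))
    th <- opt$par
  } else {
    opt <- stats::optim(th0, neg2relik, method = "Nelder-Mead",
                        control = list(reltol = tol, maxit = 1000L))
    th <- opt$par
    # restart to escape simplex collapse and tighten the optimum
    opt2 <- stats::optim(th, neg2relik, method = "Nelder-Mead",
                         control = list(reltol = 1e-15, maxit = 2000L))
    if (opt2$value <= opt$value) { th <- opt2$par; opt <- opt2 }
  }

  if (has_u) { s2u <- exp(th[1]); s2e <- exp(th[-1]) } else { s2u <- NULL; s2e <- exp(th) }
  # boundary estimates -> exact zeros
  floor_u <- 1e-8 * s2_init
  if (has_u && s2u < floor_u) s2u <- 0
  names(s2e) <- levels(strat)

  d <- s2e[sidx]
  wy <- y / d; wX <- X / d
  if (has_u && s2u > 0) {
    sg <- rowsum(1 / d, group)
    cg <- drop(s2u / (1 + s2u * sg))
    A <- rowsum(wX, group)
    ay <- rowsum(wy, group)
    XtViX <- crossprod(wX, X) - crossprod(A * sqrt(cg))
    XtViy <- crossprod(wX, y) - crossprod(A, cg * ay)
  } else {
    XtViX <- crossprod(wX, X)
    XtViy <- crossprod(wX, y)
  }
  C <- solve(XtViX)
  beta <- drop(C %*% XtViy)
  names(beta) <- colnames(X)
  dimnames(C) <- list(colnames(X), colnames(X))
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  blup <- NULL
  if (has_u) {
    if (s2u > 0) {
      qg <- rowsum(resid / d, group)
      sg <- rowsum(1 / d, group)
      blup <- drop(s2u * qg / (1 + s2u * sg))
    } else blup <- rep(0, nlevels(group))
    names(blup) <- levels(group)
  }
  list(beta = beta, vcov_beta = C, sigma2_u = if (has_u) unname(s2u) else NULL,
       sigma2_e = s2e, blup = blup,
       logLik_reml = -0.5 * (opt$value + (n - p) * log(2 * pi)),
       fitted = fitted, residuals = resid,
       converged = opt$convergence == 0L, aliased = aliased, n = n, p = p)
}
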