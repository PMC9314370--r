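#' Linear mixed model heteroscedasticity test
#'
#' Joint maximum likelihood of the full model: fixed covariate and genotype
#' effects plus a random per-individual intercept/slope pair in the
#' genotype, whose covariance matrix `(tau1 tau2; tau2 tau3)` induces the
#' variance law `v(G) = tau1 + 2 tau2 G + tau3 G^2` (the residual error is
#' absorbed into `tau1`, with which it is not separately identifiable).
#'
#' The profiled likelihood is maximised by alternating exact steps: for
#' fixed variance parameters the fixed effects are the weighted
#' least-squares solution with weights `1 / v(g_i)`; for fixed effects the
#' variance parameters are updated by Newton-Raphson with step-halving.
#' Each step increases the joint likelihood, and the loop stops when it
#' changes by less than `tol`. The PSD constraint and the
#' chi-squared(1)/chi-squared(2) boundary mixture null are the same as in
#' [fit_variance_component]; the homoscedastic null fit is the Gaussian ML
#' of the ordinary least-squares mean model.
#'
#' @inheritParams fit_mean_model
#' @param start Optional starting [var_params] for the variance law.
#' @param max_iter Maximum outer iterations.
#' @param tol Convergence tolerance on the joint log-likelihood.
#' @return A list with `fixed` (data frame of fixed-effect estimates and
#'   standard errors, genotype last) and `het` (a [het_test_result] with
#'   `method = "lmm"`).
#' @export
fit_lmm <- function(y, X, g, start = NULL, max_iter = 50L, tol = 1e-8) {
  y <- trait_values(y)
  X <- as.matrix(X)
  g <- as.numeric(g)
  n <- length(y)
  if (stats::sd(g) == 0) stop("monomorphic genotype: constant g")
  Z <- cbind(X, g = g)
  p <- ncol(Z)
  qz <- qr(Z)
  if (qz$rank < p) stop("rank-deficient design matrix")
  beta <- qr.coef(qz, y)
  r <- qr.resid(qz, y)
  rss <- sum(r^2)
  if (rss <= 1e-12 * max(1, sum(y^2)))
    stop("degenerate fit: zero residual variance under the mean model")
  ll0 <- -n / 2 * (log(2 * pi * rss / n) + 1)

  u0 <- r^2
  if (is.null(start))
    start <- fit_ols_squared(residual_set(r, g))$tau
  tau <- repair_start(as_tau3(start), g, u0)

  ll <- -Inf
  converged <- FALSE
  iter <- 0L
  psd_active <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    # variance step given current residuals (few NR passes suffice)
    vf <- fit_var_ml(r^2, g, tau, max_iter = 25L, tol = tol)
    tau <- vf$tau
    if (!is_psd_tau(tau)) {
      psd_active <- TRUE
      vf <- fit_var_ml_psd(r^2, g, tau, max_iter = 25L, tol = tol)
      tau <- vf$tau
    }
    v <- variance_at(tau, g)
    # fixed-effect step: weighted least squares at the current weights
    w <- 1 / v
    fit <- stats::lm.wfit(Z, y, w)
    beta <- fit$coefficients
    r <- fit$residuals
    ll_new <- ll_var(r^2, v)
    if (is.finite(ll) && abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- vf$converged
      break
    }
    ll <- ll_new
  }

  v <- variance_at(tau, g)
  covb <- tryCatch(solve(crossprod(Z, Z / v)), error = function(e)
    matrix(NA_real_, p, p))
  fixed <- data.frame(term = colnames(Z),
                      estimate = unname(beta),
                      se = sqrt(diag(covb)),
                      row.names = NULL)
  lrt <- max(0, 2 * (ll - ll0))
  het <- het_test_result("lmm",
                         var_params(tau[1L], tau[2L], tau[3L],
                                    psd_constrained = TRUE),
                         ll0, ll, lrt, "mixture_1_2",
                         mixture_pvalue(lrt), pseudo_r2(lrt, n),
                         converged, iter, n,
                         extra = list(psd_boundary = psd_active))
  list(fixed = fixed, het = het)
}
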