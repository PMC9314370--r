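#' @title Heteroscedasticity test result
#'
#' @description Common container returned by the four variance tests and the
#' Levene (Brown-Forsythe) comparison. Holds the fitted variance law, the
#' log-likelihoods under the homoscedastic null and the heteroscedastic
#' alternative, the likelihood-ratio statistic, the p-value computed under
#' the method's reference distribution, and the likelihood-ratio
#' pseudo-R-squared.
#'
#' The null hypothesis in every case is `tau2 = tau3 = 0` (no
#' genotype-dependent variance). Reference distributions differ by method:
#' the constrained maximum-likelihood fits (`vc`, `lmm`) use the 0.5:0.5
#' mixture of chi-squared distributions with 1 and 2 df that arises when the
#' PSD boundary is active under the null; the unconstrained regressions
#' (`ols`, `chi2`) use chi-squared with 2 df; Levene uses an F reference.
#'
#' @param method One of `"lmm"`, `"vc"`, `"ols"`, `"chi2"`, `"levene"`.
#' @param tau A [var_params] object, or `NULL` (Levene).
#' @param loglik_null,loglik_alt Log-likelihoods (Levene: `NA`).
#' @param lrt Likelihood-ratio statistic, clamped at zero.
#' @param df_rule `"mixture_1_2"`, `"chisq_2"` or `"f_levene"`.
#' @param p_het P-value of the heteroscedasticity test.
#' @param r2_het Pseudo-R-squared of the heteroscedasticity effect.
#' @param converged Logical convergence flag.
#' @param n_iter Number of iterations used.
#' @param n Sample size.
#' @param extra Optional named list of method-specific fields.
#' @return An object of class `het_test_result`.
#' @export
het_test_result <- function(method, tau, loglik_null, loglik_alt, lrt,
                            df_rule, p_het, r2_het, converged, n_iter, n,
                            extra = list()) {
  method <- match.arg(method, c("lmm", "vc", "ols", "chi2", "levene"))
  df_rule <- match.arg(df_rule, c("mixture_1_2", "chisq_2", "f_levene"))
  if (!is.na(lrt) && lrt < -1e-8)
    stop("negative likelihood-ratio statistic beyond numerical tolerance")
  if (!is.na(lrt)) lrt <- max(0, lrt)
  out <- c(list(method = method, tau = tau, loglik_null = loglik_null,
                loglik_alt = loglik_alt, lrt = lrt, df_rule = df_rule,
                p_het = p_het, r2_het = r2_het, converged = converged,
                n_iter = as.integer(n_iter), n = as.integer(n)),
           extra)
  structure(out, class = "het_test_result")
}

#' @export
print.het_test_result <- function(x, ...) {
  lab <- c(lmm = "linear mixed model", vc = "variance component model",
           ols = "quadratic Breusch-Pagan regression",
           chi2 = "chi-square regression",
           levene = "Levene (Brown-Forsythe) test")[[x$method]]
  cat("Heteroscedasticity test:", lab, "\n")
  if (!is.null(x$tau)) print(x$tau)
  if (!is.na(x$lrt))
    cat(sprintf("  LRT = %.4f  (null rule: %s)\n", x$lrt, x$df_rule))
  if (!is.null(x$statistic))
    cat(sprintf("  F = %.4f on (%d, %d) df\n",
                x$statistic, x$df1, x$df2))
  cat(sprintf("  p = %.4g   pseudo-R2 = %.4g\n", x$p_het,
              ifelse(is.na(x$r2_het), NA, x$r2_het)))
  if (!is.null(x$converged) && !isTRUE(x$converged))
    cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' Log-likelihood of the genotype-dependent variance model
#'
#' Evaluates the log-likelihood of mean-model residuals under the variance
#' law `v(G) = tau1 + 2 tau2 G + tau3 G^2` with independent zero-mean normal
#' errors:
#' \deqn{\ell(\tau) = \sum_i -\tfrac12\log(2\pi v(g_i)) - \hat e_i^2 / (2 v(g_i)).}
#'
#' The same likelihood can be written for the squared residuals as a scaled
#' chi-squared (equivalently gamma, shape 1/2, scale `2 v(G)`) regression;
#' `model = "chisq"` evaluates it through that route (gamma log-density of
#' `e^2` plus the Jacobian of the change of variable). The two forms agree
#' identically, which is why the chi-square regression and the
#' variance-component model share one likelihood surface.
#'
#' @param resid A [residual_set].
#' @param tau A [var_params] or numeric `c(tau1, tau2, tau3)`.
#' @param model `"normal"` (direct) or `"chisq"` (gamma-density route).
#' @return The log-likelihood (a single number).
#' @examples
#' rs <- residual_set(c(0, 0), c(0, 1))
#' loglik_variance_model(rs, var_params(1))  # -log(2*pi)
#' @export
loglik_variance_model <- function(resid, tau, model = c("normal", "chisq")) {
  model <- match.arg(model)
  stopifnot(inherits(resid, "residual_set"))
  v <- variance_at(tau, resid$genotype)
  if (any(v <= 0))
    stop("infeasible variance parameters: v(g) <= 0 at an observed genotype")
  e <- resid$residuals
  if (model == "normal") {
    sum(-0.5 * log(2 * pi * v) - e^2 / (2 * v))
  } else {
    # gamma(shape 1/2, scale 2 v) density of e^2, plus the log-Jacobian
    # |d(e^2)/de| / 2 = |e| of the two-branch change of variable
    u <- e^2
    sum(stats::dgamma(u, shape = 0.5, scale = 2 * v, log = TRUE)) +
      sum(0.5 * log(u))
  }
}

# internal: -Inf instead of error, for optimisers
ll_var <- function(u, v) {
  if (any(v <= 0) || any(!is.finite(v))) return(-Inf)
  sum(-0.5 * log(2 * pi * v) - u / (2 * v))
}

#' Homoscedastic null fit of the variance model
#'
#' Maximum likelihood under `tau2 = tau3 = 0`: the variance is constant and
#' its ML estimate is the mean squared residual.
#'
#' @param resid A [residual_set].
#' @return A list with `tau1_hat` and `loglik_null`.
#' @examples
#' fit_null_variance(residual_set(c(1, -1, 2, -2), c(0, 1, 1, 2)))
#' @export
fit_null_variance <- function(resid) {
  stopifnot(inherits(resid, "residual_set"))
  n <- resid$n
  if (n < 2L) stop("need at least two residuals")
  tau1 <- mean(resid$residuals^2)
  if (tau1 <= 0) stop("all residuals are zero: degenerate variance")
  list(tau1_hat = tau1,
       loglik_null = -n / 2 * (log(2 * pi * tau1) + 1))
}

#' Mixture null p-value for the constrained variance tests
#'
#' Under the null `tau2 = tau3 = 0` the PSD-constrained likelihood-ratio
#' statistic follows a 0.5:0.5 mixture of chi-squared distributions with 1
#' and 2 degrees of freedom (the null lies on the boundary of the parameter
#' cone).
#'
#' @param q Nonnegative statistic value (vectorised).
#' @return `0.5 * S_chisq1(q) + 0.5 * S_chisq2(q)`.
#' @examples
#' mixture_pvalue(0)      # 1
#' mixture_pvalue(3.841)  # ~0.0982
#' @export
mixture_pvalue <- function(q) {
  if (any(q < 0)) stop("mixture_pvalue: statistic must be nonnegative")
  0.5 * stats::pchisq(q, df = 1, lower.tail = FALSE) +
    0.5 * stats::pchisq(q, df = 2, lower.tail = FALSE)
}

#' Likelihood-ratio pseudo-R-squared
#'
#' Variance-explained measure derived from the likelihood ratio
#' (Cox-Snell/Magee form): `1 - exp(-lrt / n)`.
#'
#' @param lrt Nonnegative likelihood-ratio statistic (vectorised).
#' @param n Sample size.
#' @return Pseudo-R-squared in `[0, 1)`.
#' @examples
#' pseudo_r2(10, 1000)  # ~0.00995
#' @export
pseudo_r2 <- function(lrt, n) {
  if (any(n < 1)) stop("pseudo_r2: n must be at least 1")
  if (any(lrt < 0)) stop("pseudo_r2: lrt must be nonnegative")
  1 - exp(-lrt / n)
}

#' Quadratic Breusch-Pagan regression of squared residuals
#'
#' Ordinary least squares of the squared residuals on `(1, 2G, G^2)`, a
#' quadratic extension of the Breusch-Pagan auxiliary regression, so the
#' coefficients estimate `(tau1, tau2, tau3)` directly and unconstrained.
#' The joint test of `tau2 = tau3 = 0` uses the Gaussian likelihood-ratio
#' statistic `n log(RSS0 / RSS1)` against the intercept-only fit, referred
#' to chi-squared with 2 df. Besides being a test, the estimates serve as
#' starting values for the iterative likelihood fits.
#'
#' @param resid A [residual_set].
#' @param g Genotype vector; defaults to the one stored in `resid`.
#' @return A [het_test_result] with `method = "ols"`.
#' @export
fit_ols_squared <- function(resid, g = resid$genotype) {
  stopifnot(inherits(resid, "residual_set"))
  n <- resid$n
  u <- resid$residuals^2
  X <- variance_design(g)
  if (length(unique(g)) < 3L)
    stop("genotype takes fewer than 3 distinct values: G and G^2 collinear")
  qx <- qr(X)
  if (qx$rank < 3L) stop("collinear variance design")
  beta <- qr.coef(qx, u)
  res1 <- qr.resid(qx, u)
  rss1 <- sum(res1^2)
  rss0 <- sum((u - mean(u))^2)
  if (rss0 <= 1e-300) {           # squared residuals constant
    lrt <- 0
    ll0 <- ll1 <- NA_real_
  } else {
    rss1 <- max(rss1, 1e-300)
    lrt <- max(0, n * log(rss0 / rss1))
    ll0 <- -n / 2 * (log(2 * pi * rss0 / n) + 1)
    ll1 <- -n / 2 * (log(2 * pi * rss1 / n) + 1)
  }
  p <- stats::pchisq(lrt, df = 2, lower.tail = FALSE)
  het_test_result("ols",
                  var_params(beta[1L], beta[2L], beta[3L]),
                  ll0, ll1, lrt, "chisq_2", p, pseudo_r2(lrt, n),
                  converged = TRUE, n_iter = 0L, n = n)
}

# Repair an infeasible start by inflating tau1 until min v(g) clears a
# floor proportional to the residual variance.
repair_start <- function(tau, g, u) {
  tau <- as_tau3(tau)
  floor_v <- 1e-8 * max(mean(u), 1e-12)
  minv <- min(variance_at(tau, g))
  if (minv < floor_v) tau[1L] <- tau[1L] + (floor_v - minv)
  tau
}

# Unconstrained Newton-Raphson (Fisher-scoring fallback) maximisation of
# ll_var over tau, with step-halving. u = squared residuals.
fit_var_ml <- function(u, g, tau0, max_iter = 50L, tol = 1e-8,
                       max_halvings = 20L) {
  X <- variance_design(g)
  tau <- as_tau3(tau0)
  v <- drop(X %*% tau)
  ll <- ll_var(u, v)
  if (!is.finite(ll)) stop("infeasible starting values for variance ML")
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    grad <- 0.5 * drop(crossprod(X, (u - v) / v^2))
    wH <- 0.5 / v^2 - u / v^3
    H <- crossprod(X, X * wH)
    step <- NULL
    ok_nd <- !inherits(try(chol(-H), silent = TRUE), "try-error")
    if (ok_nd) step <- tryCatch(solve(-H, grad), error = function(e) NULL)
    if (is.null(step)) {          # Fisher scoring: expected information
      I <- crossprod(X, X * (0.5 / v^2))
      step <- tryCatch(solve(I, grad), error = function(e) grad / max(diag(I)))
    }
    ll_new <- -Inf
    lambda <- 1
    for (h in seq_len(max_halvings + 1L)) {
      tau_try <- tau + lambda * step
      v_try <- drop(X %*% tau_try)
      ll_new <- ll_var(u, v_try)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
    }
    if (!is.finite(ll_new) || ll_new < ll - 1e-12) break  # stuck
    tau <- tau + lambda * step
    v <- drop(X %*% tau)
    if (abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  list(tau = tau, loglik = ll, converged = converged, n_iter = iter)
}

# tau(theta) under the Cholesky parameterisation
# (tau1 tau2; tau2 tau3) = L L', L = [a 0; b c]
tau_of_theta <- function(theta) {
  a <- theta[1L]; b <- theta[2L]; c <- theta[3L]
  c(a * a, a * b, b * b + c * c)
}

theta_of_tau <- function(tau) {
  # Cholesky of the PSD projection (eigenvalue clipping) of the tau matrix
  M <- matrix(c(tau[1L], tau[2L], tau[2L], tau[3L]), 2L, 2L)
  ev <- eigen(M, symmetric = TRUE)
  lam <- pmax(ev$values, 1e-10 * max(abs(ev$values), 1))
  M <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
  a <- sqrt(M[1L, 1L])
  b <- M[1L, 2L] / a
  c <- sqrt(max(M[2L, 2L] - b * b, 0))
  c(a, b, c)
}

# PSD-constrained maximisation via Newton-Raphson in the Cholesky
# parameters, analytic gradient/Hessian by the chain rule; Nelder-Mead
# polish as a guarded fallback.
fit_var_ml_psd <- function(u, g, tau0, max_iter = 50L, tol = 1e-8,
                           max_halvings = 20L) {
  X <- variance_design(g)
  theta <- theta_of_tau(repair_start(tau0, g, u))
  vfun <- function(th) drop(X %*% tau_of_theta(th))
  ll <- ll_var(u, vfun(theta))
  if (!is.finite(ll)) {           # retreat to the null point
    theta <- c(sqrt(mean(u)), 0, 0)
    ll <- ll_var(u, vfun(theta))
  }
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    tau <- tau_of_theta(theta)
    v <- drop(X %*% tau)
    gt <- 0.5 * drop(crossprod(X, (u - v) / v^2))      # d ll / d tau
    wH <- 0.5 / v^2 - u / v^3
    Ht <- crossprod(X, X * wH)                         # d2 ll / d tau2
    a <- theta[1L]; b <- theta[2L]; cc <- theta[3L]
    J <- rbind(c(2 * a, 0, 0),
               c(b, a, 0),
               c(0, 2 * b, 2 * cc))                    # d tau / d theta
    grad <- drop(crossprod(J, gt))
    H <- crossprod(J, Ht %*% J)
    H[1L, 1L] <- H[1L, 1L] + 2 * gt[1L]
    H[1L, 2L] <- H[1L, 2L] + gt[2L]
    H[2L, 1L] <- H[2L, 1L] + gt[2L]
    H[2L, 2L] <- H[2L, 2L] + 2 * gt[3L]
    H[3L, 3L] <- H[3L, 3L] + 2 * gt[3L]
    step <- NULL
    if (!inherits(try(chol(-H), silent = TRUE), "try-error"))
      step <- tryCatch(solve(-H, grad), error = function(e) NULL)
    if (is.null(step))
      step <- grad / max(sum(abs(diag(H))), 1)
    ll_new <- -Inf
    lambda <- 1
    for (h in seq_len(max_halvings + 1L)) {
      th_try <- theta + lambda * step
      ll_new <- ll_var(u, vfun(th_try))
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
    }
    if (!is.finite(ll_new) || ll_new < ll - 1e-12) break
    theta <- theta + lambda * step
    if (abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  if (!converged) {               # guarded derivative-free polish
    op <- stats::optim(theta, function(th) {
      val <- ll_var(u, vfun(th))
      if (!is.finite(val)) 1e300 else -val
    }, method = "Nelder-Mead",
    control = list(maxit = 500L, reltol = 1e-12))
    if (-op$value > ll + 1e-10) {
      theta <- op$par
      ll <- -op$value
      converged <- op$convergence == 0L
    }
  }
  list(tau = tau_of_theta(theta), loglik = ll, converged = converged,
       n_iter = iter)
}

#' Chi-square regression of squared residuals
#'
#' Models the squared residual as `(tau1 + 2 tau2 G + tau3 G^2)` times a
#' chi-squared(1) variable and fits `(tau1, tau2, tau3)` unconstrained by
#' maximum likelihood (Newton-Raphson with step-halving), starting from the
#' quadratic Breusch-Pagan estimates. Its likelihood coincides with the
#' variance-component model's, so this is the unconstrained ML variance
#' test; the joint null `tau2 = tau3 = 0` is referred to chi-squared, 2 df.
#'
#' @param resid A [residual_set].
#' @param g Genotype vector; defaults to the one stored in `resid`.
#' @param start Optional starting [var_params] (defaults to
#'   [fit_ols_squared] estimates; infeasible starts are repaired by
#'   inflating `tau1`).
#' @param max_iter,tol Newton-Raphson controls.
#' @return A [het_test_result] with `method = "chi2"`.
#' @export
fit_chisq_regression <- function(resid, g = resid$genotype, start = NULL,
                                 max_iter = 50L, tol = 1e-8) {
  stopifnot(inherits(resid, "residual_set"))
  n <- resid$n
  u <- resid$residuals^2
  if (is.null(start)) start <- fit_ols_squared(resid, g)$tau
  tau0 <- repair_start(as_tau3(start), g, u)
  null_fit <- fit_null_variance(resid)
  mf <- fit_var_ml(u, g, tau0, max_iter = max_iter, tol = tol)
  lrt <- max(0, 2 * (mf$loglik - null_fit$loglik_null))
  p <- stats::pchisq(lrt, df = 2, lower.tail = FALSE)
  het_test_result("chi2",
                  var_params(mf$tau[1L], mf$tau[2L], mf$tau[3L]),
                  null_fit$loglik_null, mf$loglik, lrt, "chisq_2", p,
                  pseudo_r2(lrt, n), mf$converged, mf$n_iter, n)
}

#' Variance-component model test
#'
#' Maximum-likelihood fit of the genotype-dependent variance law to
#' mean-model residuals under the constraint that
#' `rbind(c(tau1, tau2), c(tau2, tau3))` is positive semidefinite (it is the
#' covariance matrix of the bivariate-normal random effects). The PSD
#' constraint is enforced through a Cholesky parameterisation; when the
#' unconstrained optimum already satisfies it (the usual case) the two fits
#' coincide. The likelihood-ratio statistic against the homoscedastic null
#' is referred to the 0.5:0.5 chi-squared(1)/chi-squared(2) boundary
#' mixture. This is the primary scan test.
#'
#' @inheritParams fit_chisq_regression
#' @return A [het_test_result] with `method = "vc"`.
#' @export
fit_variance_component <- function(resid, g = resid$genotype, start = NULL,
                                   max_iter = 50L, tol = 1e-8) {
  stopifnot(inherits(resid, "residual_set"))
  n <- resid$n
  u <- resid$residuals^2
  if (is.null(start)) start <- fit_ols_squared(resid, g)$tau
  tau0 <- repair_start(as_tau3(start), g, u)
  null_fit <- fit_null_variance(resid)
  mf <- fit_var_ml(u, g, tau0, max_iter = max_iter, tol = tol)
  psd_active <- FALSE
  if (!is_psd_tau(mf$tau)) {
    psd_active <- TRUE
    mf <- fit_var_ml_psd(u, g, mf$tau, max_iter = max_iter, tol = tol)
  }
  lrt <- max(0, 2 * (mf$loglik - null_fit$loglik_null))
  p <- mixture_pvalue(lrt)
  het_test_result("vc",
                  var_params(mf$tau[1L], mf$tau[2L], mf$tau[3L],
                             psd_constrained = TRUE),
                  null_fit$loglik_null, mf$loglik, lrt, "mixture_1_2", p,
                  pseudo_r2(lrt, n), mf$converged, mf$n_iter, n,
                  extra = list(psd_boundary = psd_active))
}

#' Levene (Brown-Forsythe) variance-equality test
#'
#' Nonparametric comparison test on hard-called genotype groups: absolute
#' deviations of the residuals from their genotype-group medians are
#' compared across groups by one-way ANOVA. Groups with fewer than 2 members
#' are dropped; at least two usable groups are required.
#'
#' @param resid A [residual_set].
#' @param hard_calls Integer genotypes in `{0, 1, 2}` (defaults to
#'   hard-calling the stored dosages).
#' @return A [het_test_result] with `method = "levene"`, carrying the F
#'   statistic and its degrees of freedom in `statistic`, `df1`, `df2`
#'   (`lrt`, log-likelihoods and `r2_het` are `NA`: the test is not
#'   likelihood-based).
#' @export
levene_bf <- function(resid, hard_calls = hard_call(resid$genotype)) {
  stopifnot(inherits(resid, "residual_set"))
  e <- resid$residuals
  gfac <- factor(hard_calls)
  keep <- gfac %in% names(which(table(gfac) >= 2L))
  e <- e[keep]
  gfac <- droplevels(gfac[keep])
  k <- nlevels(gfac)
  if (k < 2L) stop("fewer than 2 genotype groups with >= 2 members")
  z <- abs(e - stats::ave(e, gfac, FUN = stats::median))
  N <- length(z)
  zbar <- mean(z)
  gm <- tapply(z, gfac, mean)
  ng <- tapply(z, gfac, length)
  ssb <- sum(ng * (gm - zbar)^2)
  ssw <- sum((z - stats::ave(z, gfac, FUN = mean))^2)
  df1 <- k - 1L
  df2 <- N - k
  f <- if (ssw <= 1e-300) {
    if (ssb <= 1e-300) 0 else Inf
  } else (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  het_test_result("levene", NULL, NA_real_, NA_real_, NA_real_,
                  "f_levene", p, NA_real_, TRUE, 0L, N,
                  extra = list(statistic = f, df1 = df1, df2 = df2))
}
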