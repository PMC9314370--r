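#' Fit the mean model and extract residuals
#'
#' Ordinary least squares of the trait on the covariates plus the additive
#' genotype term, as in a standard GWAS. Reports the per-allele effect, its
#' standard error, a two-sided p-value (t reference with `n - p` df, which
#' is the normal reference at biobank sample sizes), the partial
#' R-squared of the genotype after covariates, and the residuals consumed
#' by the variance tests.
#'
#' @param y Trait values (numeric vector or [trait_vector]).
#' @param X Covariate design matrix including the intercept column.
#' @param g Genotype vector (dosage in `[0, 2]` or hard calls).
#' @return A list with components `main` (class `main_effect_result`:
#'   `beta_g`, `se`, `p_main`, `r2_main`, `rss_cov`, `rss_full`, `n`,
#'   `degenerate`) and `resid` (a [residual_set]).
#' @examples
#' set.seed(1)
#' g <- rbinom(50, 2, 0.3)
#' y <- 1 + 0.5 * g + rnorm(50)
#' fit_mean_model(y, cbind(1, rnorm(50)), g)$main$beta_g
#' @export
fit_mean_model <- function(y, X, g) {
  y <- trait_values(y)
  X <- as.matrix(X)
  g <- as.numeric(g)
  n <- length(y)
  if (nrow(X) != n || length(g) != n)
    stop("y, X and g must have matching lengths")
  if (anyNA(y) || anyNA(X) || anyNA(g))
    stop("missing values: apply complete-case filtering first")
  if (stats::sd(g) == 0) stop("monomorphic genotype: constant g")
  Z <- cbind(X, g = g)
  p <- ncol(Z)
  if (n <= p) stop("more parameters than samples")
  qz <- qr(Z)
  if (qz$rank < p) stop("rank-deficient design matrix")
  beta <- qr.coef(qz, y)
  res <- qr.resid(qz, y)
  rss_full <- sum(res^2)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient covariate matrix")
  rss_cov <- sum(qr.resid(qx, y)^2)
  degenerate <- rss_full <= 1e-12 * max(1, sum(y^2))
  sigma2 <- rss_full / (n - p)
  R <- qr.R(qz)
  cov0 <- chol2inv(R)
  cov <- matrix(NA_real_, p, p)
  cov[qz$pivot, qz$pivot] <- cov0
  se_g <- sqrt(sigma2 * cov[p, p])
  tstat <- unname(beta[p]) / se_g
  p_main <- 2 * stats::pt(-abs(tstat), df = n - p)
  main <- structure(list(beta_g = unname(beta[p]), se = se_g,
                         p_main = p_main,
                         r2_main = partial_r2(rss_cov, rss_full),
                         rss_cov = rss_cov, rss_full = rss_full,
                         n = n, degenerate = degenerate,
                         coefficients = beta),
                    class = "main_effect_result")
  list(main = main, resid = residual_set(res, g))
}

#' @export
print.main_effect_result <- function(x, ...) {
  cat(sprintf(
    "main effect: beta_g = %.6g (se %.4g), p = %.4g, partial R2 = %.4g, n = %d\n",
    x$beta_g, x$se, x$p_main, x$r2_main, x$n))
  if (x$degenerate) cat("  WARNING: zero residual variance (exact fit)\n")
  invisible(x)
}

#' Partial R-squared of the genotype after covariates
#'
#' `(rss_cov - rss_full) / rss_cov`: the share of covariate-adjusted trait
#' variance removed by adding the genotype to the mean model.
#'
#' @param rss_cov Residual sum of squares of the covariate-only model.
#' @param rss_full Residual sum of squares of the model with the genotype.
#' @return Partial R-squared in `[0, 1)`.
#' @export
partial_r2 <- function(rss_cov, rss_full) {
  if (rss_full < 0 || rss_cov <= 0) stop("residual sums of squares invalid")
  if (rss_full > rss_cov * (1 + 1e-12))
    stop("rss_full exceeds rss_cov: models not nested")
  max(0, (rss_cov - rss_full) / rss_cov)
}
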