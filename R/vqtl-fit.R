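#' Fit the vQTL model for a single variant
#'
#' One-stop fitting interface: ordinary least squares for the mean model
#' (covariates + additive genotype, the standard-GWAS main effect),
#' followed by the requested heteroscedasticity test(s) on the residuals.
#' Returns a classed object with the usual accessor methods.
#'
#' Either supply `y` as a numeric vector (or [trait_vector]) together with
#' a covariate matrix `X`, or supply a formula and `data`, in which case
#' the model frame provides the trait and covariates and `g` may be the
#' name of a genotype column in `data`.
#'
#' @param y Trait values, or a formula such as `sbp ~ sex + age + bmi`.
#' @param g Genotype vector (dosage or hard calls), or a column name in
#'   `data` when `y` is a formula.
#' @param X Covariate matrix; an intercept column is added if none is
#'   present. Ignored when `y` is a formula.
#' @param method Heteroscedasticity test(s) to run: `"vc"` (default
#'   primary analysis), `"lmm"`, `"ols"`, `"chi2"`, `"levene"` or `"all"`.
#' @param data Data frame for the formula interface.
#' @return An object of class `vqtl_fit`: a list with `main`
#'   (main-effect statistics), `het` (named list of [het_test_result]),
#'   `resid` (a [residual_set]), `lmm_fixed` (when `method` includes
#'   `"lmm"`), `n`, and `call`.
#' @examples
#' set.seed(7)
#' n <- 400
#' g <- rbinom(n, 2, 0.3)
#' X <- cbind(1, rnorm(n))
#' y <- 1 + 0.2 * X[, 2] - 0.3 * g + rnorm(n, 0, sqrt(1 + 0.5 * g^2))
#' fit <- vqtl_fit(y, g, X, method = "vc")
#' print(fit)
#' @export
vqtl_fit <- function(y, g, X = NULL, method = "vc", data = NULL) {
  cl <- match.call()
  method <- match.arg(method,
                      c("vc", "lmm", "ols", "chi2", "levene", "all"))
  if (inherits(y, "formula")) {
    if (is.null(data)) stop("formula interface requires data")
    mf <- stats::model.frame(y, data)
    X <- stats::model.matrix(attr(mf, "terms"), mf)
    yv <- stats::model.response(mf)
    if (is.character(g)) g <- data[[g]]
  } else {
    yv <- trait_values(y)
    if (is.null(X)) X <- matrix(1, length(yv), 1L,
                                dimnames = list(NULL, "intercept"))
    X <- as.matrix(X)
    if (!any(apply(X, 2L, function(col) all(col == col[1L]) && col[1L] != 0)))
      X <- cbind(intercept = 1, X)
  }
  g <- as.numeric(g)
  mm <- fit_mean_model(yv, X, g)
  if (mm$main$degenerate)
    stop("degenerate mean-model fit: zero residual variance")
  methods <- scan_methods(method)
  rs <- mm$resid
  start <- fit_ols_squared(rs)$tau
  lmm_fixed <- NULL
  het <- lapply(stats::setNames(methods, methods), function(m) {
    if (m == "lmm") {
      lf <- fit_lmm(yv, X, g, start = start)
      lmm_fixed <<- lf$fixed
      lf$het
    } else run_het_test(m, rs, y = yv, X = X, start = start)
  })
  structure(list(main = mm$main, het = het, resid = rs,
                 lmm_fixed = lmm_fixed, n = mm$main$n, call = cl),
            class = "vqtl_fit")
}

primary_het <- function(x) x$het[[1L]]

#' @export
print.vqtl_fit <- function(x, ...) {
  cat("vQTL fit (n =", x$n, ")\n\n")
  print(x$main)
  cat("\n")
  for (h in x$het) print(h)
  invisible(x)
}

#' @export
summary.vqtl_fit <- function(object, ...) {
  het_tab <- do.call(rbind, lapply(object$het, function(h) {
    tau <- if (is.null(h$tau)) c(NA, NA, NA) else as_tau3(h$tau)
    data.frame(method = h$method, tau1 = tau[1L], tau2 = tau[2L],
               tau3 = tau[3L], lrt = h$lrt, p_het = h$p_het,
               r2_het = h$r2_het, converged = h$converged)
  }))
  rownames(het_tab) <- NULL
  out <- list(main = object$main, het = het_tab, n = object$n,
              call = object$call)
  class(out) <- "summary.vqtl_fit"
  out
}

#' @export
print.summary.vqtl_fit <- function(x, ...) {
  cat("Call: ")
  print(x$call)
  cat("\n")
  print(x$main)
  cat("\nHeteroscedasticity tests:\n")
  print(x$het, digits = 4)
  invisible(x)
}

#' @export
coef.vqtl_fit <- function(object, ...) {
  h <- primary_het(object)
  tau <- if (is.null(h$tau)) c(NA, NA, NA) else as_tau3(h$tau)
  c(beta_g = object$main$beta_g,
    tau1 = tau[1L], tau2 = tau[2L], tau3 = tau[3L])
}

#' @export
residuals.vqtl_fit <- function(object, ...) object$resid$residuals

#' Predicted genotype-dependent variance
#'
#' @param object A [vqtl_fit].
#' @param g Genotypes at which to evaluate the fitted variance law
#'   (default: the fitted data's genotypes).
#' @param ... Unused.
#' @return Numeric vector of fitted variances `v(g)` from the primary
#'   heteroscedasticity fit.
#' @export
predict.vqtl_fit <- function(object, g = object$resid$genotype, ...) {
  h <- primary_het(object)
  if (is.null(h$tau))
    stop("the primary method (", h$method, ") does not fit a variance law")
  variance_at(h$tau, g)
}

#' @export
plot.vqtl_fit <- function(x, ...) {
  rs <- x$resid
  graphics::plot(jitter(rs$genotype, amount = 0.04), rs$residuals^2,
                 pch = 16, cex = 0.4, col = "grey50",
                 xlab = "genotype (dosage)",
                 ylab = "squared residual",
                 main = "fitted variance law", ...)
  h <- primary_het(x)
  if (!is.null(h$tau)) {
    gg <- seq(min(rs$genotype), max(rs$genotype), length.out = 101L)
    graphics::lines(gg, variance_at(h$tau, gg), lwd = 2)
  }
  invisible(x)
}

#' Simulate residuals from a fitted vQTL variance law
#'
#' Draws new residual vectors from the fitted variance law (zero-mean
#' normal with variance `v(g)` at the fitted data's genotypes), the
#' parametric-bootstrap ingredient for the heteroscedasticity model.
#'
#' @param object A [vqtl_fit].
#' @param nsim Number of simulated trait vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns.
#' @export
simulate.vqtl_fit <- function(object, nsim = 1, seed = NULL, ...) {
  h <- primary_het(object)
  if (is.null(h$tau))
    stop("the primary method (", h$method, ") does not fit a variance law")
  rs <- object$resid
  v <- variance_at(h$tau, rs$genotype)
  with_seed(seed, {
    out <- replicate(nsim, stats::rnorm(rs$n, 0, sqrt(v)))
    as.data.frame(out)
  })
}
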