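#' Variance-law parameters
#'
#' Container for the parameters of the genotype-dependent variance law
#' \deqn{v(G) = \tau_1 + 2\tau_2 G + \tau_3 G^2,}
#' the quadratic form that the trait variance takes when a per-allele effect
#' varies across individuals (e.g. through gene-environment interaction).
#' `tau1` is the baseline residual variance (trait units squared), `tau2` the
#' covariance between the baseline and the per-allele random effect, and
#' `tau3` the variance of the per-allele effect.
#'
#' Under the bivariate-normal random-effect model the matrix
#' `rbind(c(tau1, tau2), c(tau2, tau3))` is a covariance matrix and must be
#' positive semidefinite (PSD); `psd_constrained = TRUE` records that the fit
#' enforced this. The regression-based tests leave the parameters
#' unconstrained.
#'
#' @param tau1 Baseline variance, must be positive when `psd_constrained`.
#' @param tau2 Baseline/per-allele covariance.
#' @param tau3 Variance of the per-allele effect.
#' @param psd_constrained Logical; was the PSD constraint enforced?
#' @return An object of class `var_params`.
#' @examples
#' var_params(2, 0.5, 1)
#' @export
var_params <- function(tau1, tau2 = 0, tau3 = 0, psd_constrained = FALSE) {
  stopifnot(is.numeric(tau1), is.numeric(tau2), is.numeric(tau3),
            length(tau1) == 1L, length(tau2) == 1L, length(tau3) == 1L)
  if (isTRUE(psd_constrained)) {
    scale <- max(1, tau1^2, tau2^2, abs(tau3) * tau1)
    if (tau1 < 0 || tau3 < -1e-10 * scale ||
        tau1 * tau3 - tau2^2 < -1e-10 * scale)
      stop("var_params: PSD constraint violated by supplied parameters")
  }
  structure(list(tau1 = tau1, tau2 = tau2, tau3 = tau3,
                 psd_constrained = isTRUE(psd_constrained)),
            class = "var_params")
}

#' @export
print.var_params <- function(x, ...) {
  cat(sprintf("variance law v(G) = %.6g + 2(%.6g)G + (%.6g)G^2%s\n",
              x$tau1, x$tau2, x$tau3,
              if (x$psd_constrained) "  [PSD-constrained]" else ""))
  invisible(x)
}

# numeric length-3 tau from var_params or numeric vector
as_tau3 <- function(tau) {
  if (inherits(tau, "var_params")) c(tau$tau1, tau$tau2, tau$tau3)
  else if (is.numeric(tau) && length(tau) == 3L) as.numeric(tau)
  else stop("tau must be a var_params object or a numeric vector of length 3")
}

# v(g) for a tau vector; vectorised over g
variance_at <- function(tau, g) {
  tau <- as_tau3(tau)
  tau[1L] + 2 * tau[2L] * g + tau[3L] * g * g
}

# design of the variance law: columns (1, 2g, g^2) so coefficients are tau
variance_design <- function(g) cbind(1, 2 * g, g * g)

is_psd_tau <- function(tau, tol = 1e-10) {
  tau <- as_tau3(tau)
  scale <- max(1, tau[1L]^2, tau[2L]^2, abs(tau[1L] * tau[3L]))
  tau[1L] >= 0 && tau[3L] >= -tol * scale &&
    tau[1L] * tau[3L] - tau[2L]^2 >= -tol * scale
}

#' Residuals paired with the genotype that indexes their variance
#'
#' The variance tests operate on residuals from the mean model, paired with
#' the per-sample genotype (dosage in `[0, 2]` or hard call) that enters the
#' variance law.
#'
#' @param residuals Numeric vector of mean-model residuals.
#' @param genotype Numeric vector of the same length; dosages or hard calls.
#' @return An object of class `residual_set` with elements `residuals`,
#'   `genotype` and `n`.
#' @export
residual_set <- function(residuals, genotype) {
  residuals <- as.numeric(residuals)
  genotype <- as.numeric(genotype)
  if (length(residuals) != length(genotype))
    stop("residuals and genotype must have the same length")
  if (anyNA(residuals) || anyNA(genotype))
    stop("residual_set does not accept missing values; filter first")
  structure(list(residuals = residuals, genotype = genotype,
                 n = length(residuals)),
            class = "residual_set")
}
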