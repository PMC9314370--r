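with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Counter-based seed derivation: every replicate gets its own stream seed
# reproducible in isolation from the master seed. Kept below 2^31.
derive_seed <- function(master, stream, index = 0L) {
  base <- as.numeric(master) %% 100000
  as.integer((base * 20011 + stream * 100003 + index) %% 2147483629 + 1)
}

#' Simulation specification
#'
#' Stated world for the simulation studies: a systolic-blood-pressure-like
#' trait generated from covariates, a panel of background SNPs with
#' constant effects, and one focal SNP whose per-allele effect is random
#' across individuals, `b ~ N(mu_effect, sigma2_effect)`, inducing the
#' variance law with `tau3 = sigma2_effect` and `tau2 = 0`.
#'
#' Defaults follow the fitted null SBP model (intercept 86.5, sex 5.65,
#' age-squared 0.00827, BMI 0.909, PC4 0.0647, PC9 0.0349; error SD 18.44)
#' and the focal mean effect of -0.475 mm Hg per coded allele. The 54
#' background SNP effects are placeholders drawn once from the seed (the
#' real panel is literature-specific and not part of this package); they
#' provide structural realism only. Desk-scale defaults (`n = 10000`,
#' `replicates = 300`, `alpha = 0.05`) keep runtimes in minutes;
#' `paper_scale = TRUE` switches to the biobank-scale configuration
#' (`n = 396387`, `replicates = 1000`, `alpha = 5e-8`).
#'
#' @param n Sample size per replicate.
#' @param coefficients Named vector of trait-model coefficients; names must
#'   match covariate columns (`intercept` allowed).
#' @param snp_effects Data frame with columns `maf`, `beta` for background
#'   SNPs, or `NULL` for none.
#' @param focal List with `maf`, `mu_effect`, `sigma2_effect`.
#' @param error_sd Residual SD of the trait (mm Hg).
#' @param replicates Number of Monte-Carlo replicates.
#' @param alpha Significance threshold applied to replicate p-values.
#' @param seed Master seed; all randomness derives from it.
#' @param n_background Number of placeholder background SNPs.
#' @param paper_scale Use the biobank-scale settings.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n = 10000L,
                            coefficients = c(intercept = 86.5, sex = 5.65,
                                             age2 = 0.00827, bmi = 0.909,
                                             pc4 = 0.0647, pc9 = 0.0349),
                            snp_effects = NULL,
                            focal = list(maf = 0.3, mu_effect = -0.475,
                                         sigma2_effect = 0),
                            error_sd = 18.44,
                            replicates = 300L,
                            alpha = 0.05,
                            seed = 1L,
                            n_background = 54L,
                            paper_scale = FALSE) {
  if (paper_scale) {
    n <- 396387L
    replicates <- 1000L
    alpha <- 5e-8
  }
  stopifnot(n >= 1L, replicates >= 1L, error_sd > 0,
            alpha > 0, alpha < 1,
            focal$maf > 0, focal$maf <= 0.5, focal$sigma2_effect >= 0)
  if (is.null(snp_effects) && n_background > 0L) {
    snp_effects <- with_seed(derive_seed(seed, 99L), data.frame(
      maf = stats::runif(n_background, 0.05, 0.5),
      beta = stats::rnorm(n_background, 0, 0.5)))
  }
  if (!is.null(snp_effects))
    stopifnot(all(snp_effects$maf > 0), all(snp_effects$maf <= 0.5))
  structure(list(n = as.integer(n), coefficients = coefficients,
                 snp_effects = snp_effects, focal = focal,
                 error_sd = error_sd, replicates = as.integer(replicates),
                 alpha = alpha, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(paste0("simulation_spec: n = %d, %d background SNPs, focal ",
                     "maf %.2f, effect N(%.3g, %.3g), error SD %.4g,\n",
                     "  %d replicates at alpha = %g (seed %d)\n"),
              x$n, NROW(x$snp_effects), x$focal$maf, x$focal$mu_effect,
              x$focal$sigma2_effect, x$error_sd, x$replicates, x$alpha,
              x$seed))
  invisible(x)
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Independent hard-call genotypes: the coded-allele count per sample is
#' Binomial(2, maf).
#'
#' @param n Number of samples.
#' @param maf Coded (minor) allele frequency in `(0, 0.5]`.
#' @param seed Optional seed (the global RNG state is preserved).
#' @return Integer vector in `{0, 1, 2}`.
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  if (!(maf > 0 && maf <= 0.5)) stop("maf must lie in (0, 0.5]")
  with_seed(seed, stats::rbinom(n, 2L, maf))
}

#' Simulate covariates
#'
#' Emulates the analysis covariate set: sex ~ Bernoulli(0.46), age ~
#' Uniform(40, 69) (the cohort recruitment range), age squared, BMI ~
#' Normal(27, 4.8^2) truncated positive, and 10 standard-normal principal
#' components. The distributions (other than the age range) are plumbing
#' choices, not estimates.
#'
#' @param n Number of samples.
#' @param seed Optional seed.
#' @return Numeric matrix with columns `sex`, `age`, `age2`, `bmi`,
#'   `pc1`..`pc10`.
#' @export
simulate_covariates <- function(n, seed = NULL) {
  stopifnot(n >= 1L)
  with_seed(seed, {
    sex <- stats::rbinom(n, 1L, 0.46)
    age <- stats::runif(n, 40, 69)
    bmi <- stats::rnorm(n, 27, 4.8)
    while (any(bmi <= 0)) {
      bad <- bmi <= 0
      bmi[bad] <- stats::rnorm(sum(bad), 27, 4.8)
    }
    pcs <- matrix(stats::rnorm(n * 10L), n, 10L,
                  dimnames = list(NULL, paste0("pc", 1:10)))
    cbind(sex = sex, age = age, age2 = age^2, bmi = bmi, pcs)
  })
}

#' Simulate a trait with an optionally random focal-SNP effect
#'
#' `y = intercept + covariate terms + background SNP terms + b * g_focal +
#' e`, with `e ~ N(0, error_sd^2)`. Under the null (`sigma2_effect = 0`)
#' the focal effect `b` is the constant `mu_effect`; under the alternative
#' each individual draws an independent `b_j ~ N(mu_effect,
#' sigma2_effect)`, which induces genotype-dependent trait variance
#' `v(G) = error_sd^2 + sigma2_effect * G^2` (so `tau3 = sigma2_effect`,
#' `tau2 = 0`).
#'
#' @param spec A [simulation_spec].
#' @param genotypes List with `focal` (vector) and optionally `background`
#'   (matrix, samples x SNPs, matching `spec$snp_effects`).
#' @param covariates Covariate matrix from [simulate_covariates].
#' @param seed Optional seed for the random effect and error draws.
#' @return A [trait_vector].
#' @export
simulate_trait <- function(spec, genotypes, covariates, seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n
  if (nrow(covariates) != n) stop("covariates do not match spec$n")
  cf <- spec$coefficients
  mu <- rep(if ("intercept" %in% names(cf)) cf[["intercept"]] else 0, n)
  for (nm in setdiff(names(cf), "intercept")) {
    if (!nm %in% colnames(covariates))
      stop("coefficient names a missing covariate column: ", nm)
    mu <- mu + cf[[nm]] * covariates[, nm]
  }
  if (!is.null(spec$snp_effects)) {
    bg <- genotypes$background
    if (is.null(bg) || ncol(bg) != nrow(spec$snp_effects) || nrow(bg) != n)
      stop("background genotypes do not match spec$snp_effects")
    mu <- mu + drop(bg %*% spec$snp_effects$beta)
  }
  gf <- genotypes$focal
  if (is.null(gf)) gf <- numeric(n)
  if (length(gf) != n) stop("focal genotype length mismatch")
  y <- with_seed(seed, {
    b <- if (spec$focal$sigma2_effect > 0)
      stats::rnorm(n, spec$focal$mu_effect, sqrt(spec$focal$sigma2_effect))
    else spec$focal$mu_effect
    mu + b * gf + stats::rnorm(n, 0, spec$error_sd)
  })
  trait_vector(y, "generic")
}

# genotype set (focal + background) for a spec, derived from the master seed
simulate_genotype_set <- function(spec, stream = 10L) {
  bg <- NULL
  if (!is.null(spec$snp_effects)) {
    bg <- vapply(seq_len(nrow(spec$snp_effects)), function(i)
      simulate_genotypes(spec$n, spec$snp_effects$maf[i],
                         derive_seed(spec$seed, stream, i)),
      numeric(spec$n))
  }
  focal <- simulate_genotypes(spec$n, spec$focal$maf,
                              derive_seed(spec$seed, stream + 1L))
  list(focal = focal, background = bg)
}

analysis_design <- function(covariates) {
  cbind(intercept = 1, covariates)
}

#' Null-calibration study
#'
#' Simulates one trait under the null (all SNP effects constant, so no
#' variance heteroscedasticity), then applies the requested test(s) to
#' `n_snps` freshly simulated, trait-independent SNPs, mirroring a
#' genome-wide null scan. Returns the per-SNP p-values, empirical rejection
#' rates with binomial standard errors, and QQ coordinates.
#'
#' @param spec A [simulation_spec] with `focal$sigma2_effect = 0`.
#' @param method Character vector of test methods (any of `"lmm"`, `"vc"`,
#'   `"ols"`, `"chi2"`, `"levene"`).
#' @param n_snps Number of null SNPs to test.
#' @param alphas Significance levels for the rejection-rate summary.
#' @param maf_range Range from which each tested SNP's allele frequency is
#'   drawn uniformly.
#' @return A list with `pvalues` (data frame, one column per method),
#'   `rejection` (data frame: method, alpha, rate, se) and `qq` (named list
#'   of [qq_points] frames).
#' @export
null_calibration <- function(spec, method = "vc", n_snps = 2000L,
                             alphas = c(0.01, 0.05),
                             maf_range = c(0.05, 0.45)) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$focal$sigma2_effect != 0)
    stop("null calibration requires sigma2_effect = 0")
  method <- match.arg(method, c("lmm", "vc", "ols", "chi2", "levene"),
                      several.ok = TRUE)
  covs <- simulate_covariates(spec$n, derive_seed(spec$seed, 1L))
  geno <- simulate_genotype_set(spec, stream = 2L)
  y <- simulate_trait(spec, geno, covs, derive_seed(spec$seed, 3L))
  X <- analysis_design(covs)
  mafs <- with_seed(derive_seed(spec$seed, 4L),
                    stats::runif(n_snps, maf_range[1L], maf_range[2L]))
  pv <- matrix(NA_real_, n_snps, length(method),
               dimnames = list(NULL, method))
  for (j in seq_len(n_snps)) {
    g <- simulate_genotypes(spec$n, mafs[j], derive_seed(spec$seed, 5L, j))
    if (length(unique(g)) < 3L) next
    mm <- fit_mean_model(y, X, g)
    rs <- mm$resid
    start <- fit_ols_squared(rs)$tau
    for (m in method)
      pv[j, m] <- run_het_test(m, rs, y = y, X = X, start = start)$p_het
  }
  ok <- stats::complete.cases(pv)
  pv <- pv[ok, , drop = FALSE]
  rej <- do.call(rbind, lapply(method, function(m) {
    data.frame(method = m, alpha = alphas,
               rate = vapply(alphas, function(a) mean(pv[, m] < a),
                             numeric(1)),
               se = sqrt(alphas * (1 - alphas) / nrow(pv)))
  }))
  qq <- lapply(stats::setNames(method, method),
               function(m) qq_points(pv[, m]))
  list(pvalues = as.data.frame(pv), rejection = rej, qq = qq)
}

#' Empirical power of the heteroscedasticity tests
#'
#' For each value of the effect-variance grid, simulates `spec$replicates`
#' traits with the focal per-allele effect drawn per individual from
#' `N(mu_effect, sigma2)`, tests the focal SNP with each requested method,
#' and reports the fraction of replicates significant at `spec$alpha`.
#' Covariates and genotypes are simulated once and held fixed across
#' replicates (as when real cohort data are reused); only the random
#' effects and errors are redrawn, from per-replicate seeds derived from
#' the master seed.
#'
#' @param spec A [simulation_spec].
#' @param method Character vector of test methods.
#' @param sigma2_grid Heteroscedasticity levels (variances of the focal
#'   per-allele effect).
#' @return A data frame with columns `sigma2`, `method`, `power`, `mc_se`,
#'   `replicates`.
#' @export
estimate_power <- function(spec, method = "vc",
                           sigma2_grid = c(1, 2, 3, 4, 5)) {
  stopifnot(inherits(spec, "simulation_spec"), length(sigma2_grid) >= 1L)
  method <- match.arg(method, c("lmm", "vc", "ols", "chi2", "levene"),
                      several.ok = TRUE)
  covs <- simulate_covariates(spec$n, derive_seed(spec$seed, 11L))
  geno <- simulate_genotype_set(spec, stream = 12L)
  X <- analysis_design(covs)
  g <- geno$focal
  qz <- qr(cbind(X, g))
  out <- vector("list", length(sigma2_grid) * length(method))
  k <- 0L
  for (si in seq_along(sigma2_grid)) {
    s2 <- sigma2_grid[si]
    spec_s <- spec
    spec_s$focal$sigma2_effect <- s2
    hits <- matrix(FALSE, spec$replicates, length(method),
                   dimnames = list(NULL, method))
    for (r in seq_len(spec$replicates)) {
      y <- simulate_trait(spec_s, geno, covs,
                          derive_seed(spec$seed, 20L + si, r))
      res <- qr.resid(qz, y$values)
      rs <- residual_set(res, g)
      start <- fit_ols_squared(rs)$tau
      for (m in method) {
        p <- run_het_test(m, rs, y = y, X = X, start = start)$p_het
        hits[r, m] <- is.finite(p) && p < spec$alpha
      }
    }
    for (m in method) {
      k <- k + 1L
      pw <- mean(hits[, m])
      out[[k]] <- data.frame(sigma2 = s2, method = m, power = pw,
                             mc_se = sqrt(pw * (1 - pw) / spec$replicates),
                             replicates = spec$replicates)
    }
  }
  do.call(rbind, out)
}
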