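test_that("variance-model log-likelihood matches closed forms and the gamma route", {
  # zero residuals, unit variance: each term is -log(2*pi)/2
  rs0 <- residual_set(c(0, 0), c(0, 1))
  expect_equal(loglik_variance_model(rs0, var_params(1)), -log(2 * pi))

  # the normal form equals gamma(shape 1/2, scale 2v) density of e^2 plus
  # the change-of-variable Jacobian, for random feasible parameters
  rs <- make_het_resid(200, tau = c(2, 0.2, 0.6), seed = 3)
  for (i in 1:20) {
    tau <- withr::with_seed(100 + i,
                            c(runif(1, 0.5, 3), runif(1, -0.3, 0.3),
                              runif(1, 0, 1)))
    ll_normal <- loglik_variance_model(rs, tau)
    u <- rs$residuals^2
    v <- tau[1] + 2 * tau[2] * rs$genotype + tau[3] * rs$genotype^2
    ll_gamma <- sum(dgamma(u, shape = 0.5, scale = 2 * v, log = TRUE)) +
      sum(0.5 * log(u))
    expect_equal(ll_normal, ll_gamma, tolerance = 1e-12)
    expect_equal(loglik_variance_model(rs, tau, model = "chisq"), ll_gamma,
                 tolerance = 1e-12)
  }

  # infeasible parameters signal an error
  expect_error(loglik_variance_model(rs0, var_params(1, 0, -2)),
               "infeasible")
})

test_that("homoscedastic null fit is the mean squared residual", {
  rs <- residual_set(c(1, -1, 2, -2), c(0, 1, 1, 2))
  nf <- fit_null_variance(rs)
  expect_equal(nf$tau1_hat, 2.5)
  # closed form: -n/2 (log(2 pi tau1) + 1)
  expect_equal(nf$loglik_null, -2 * (log(2 * pi * 2.5) + 1))
  expect_equal(nf$loglik_null, -7.5086, tolerance = 1e-4)

  # scale equivariance: residuals scaled by c multiply tau1 by c^2
  rs2 <- residual_set(3 * rs$residuals, rs$genotype)
  expect_equal(fit_null_variance(rs2)$tau1_hat, 9 * 2.5)

  expect_error(fit_null_variance(residual_set(c(0, 0), c(0, 1))),
               "zero")
})

test_that("saturated three-group data give the closed-form tau for all fitters", {
  rs <- saturated_example()
  # group means of e^2 are (2, 4, 8); solving v(0)=2, v(1)=4, v(2)=8
  # gives tau = (2, 0.5, 1); LRT = sum log(sigma0^2 / vhat) with
  # sigma0^2 = 14/3
  tau_true <- c(2, 0.5, 1)
  lrt_true <- 6 * log(14 / 3) - 2 * log(2 * 4 * 8)

  ols <- fit_ols_squared(rs)
  expect_equal(as.numeric(unlist(ols$tau[1:3])), tau_true, tolerance = 1e-10)

  chi2 <- fit_chisq_regression(rs)
  expect_true(chi2$converged)
  expect_equal(as.numeric(unlist(chi2$tau[1:3])), tau_true, tolerance = 1e-6)
  expect_equal(chi2$lrt, lrt_true, tolerance = 1e-6)
  expect_equal(chi2$lrt, 0.9249, tolerance = 1e-3)
  # chi-squared 2 df survival has closed form exp(-q/2)
  expect_equal(chi2$p_het, exp(-lrt_true / 2), tolerance = 1e-6)

  # (2, 0.5, 1) has determinant 1.75 > 0: the PSD constraint is inactive
  # and the variance-component fit lands on the same point
  vc <- fit_variance_component(rs)
  expect_equal(as.numeric(unlist(vc$tau[1:3])), tau_true, tolerance = 1e-6)
  expect_equal(vc$lrt, chi2$lrt, tolerance = 1e-6)
  expect_equal(vc$p_het,
               0.5 * pchisq(lrt_true, 1, lower.tail = FALSE) +
                 0.5 * exp(-lrt_true / 2), tolerance = 1e-6)
})

test_that("degenerate and start-quality paths of the ML fitters behave", {
  # constant squared residuals: no heteroscedasticity signal at all
  rs_const <- residual_set(c(1, -1, 1, -1, 1, -1), c(0, 0, 1, 1, 2, 2))
  ols <- fit_ols_squared(rs_const)
  expect_equal(ols$lrt, 0)
  expect_equal(ols$p_het, 1)

  # ascent property: optimum log-likelihood is at least the start's
  rs <- make_het_resid(500, tau = c(1, 0.1, 0.4), seed = 9)
  start <- fit_ols_squared(rs)$tau
  chi2 <- fit_chisq_regression(rs, start = start)
  ll_start <- loglik_variance_model(
    rs, vqtlscan:::repair_start(vqtlscan:::as_tau3(start), rs$genotype,
                                rs$residuals^2))
  expect_gte(chi2$loglik_alt, ll_start - 1e-10)

  # fewer than three distinct genotypes: G and G^2 collinear
  rs2 <- residual_set(rnorm(10), rep(c(0, 1), 5))
  expect_error(fit_ols_squared(rs2), "distinct")
})

test_that("unconstrained ML is consistent under the null and recovers tau3", {
  # under homoscedastic null, tau2 and tau3 shrink toward zero
  rs <- make_het_resid(20000, tau = c(1, 0, 0), seed = 21)
  chi2 <- fit_chisq_regression(rs)
  expect_lt(abs(chi2$tau$tau2), 0.05)
  expect_lt(abs(chi2$tau$tau3), 0.05)
  expect_equal(chi2$tau$tau1, 1, tolerance = 0.1)

  # with a genotype-dependent effect, tau3_hat tracks its variance
  rs <- make_het_resid(20000, tau = c(1, 0, 0.8), seed = 22)
  vc <- fit_variance_component(rs)
  expect_equal(vc$tau$tau3, 0.8, tolerance = 0.25)
  expect_true(vc$converged)
})

test_that("PSD constraint can only lower the likelihood ratio", {
  # decreasing-variance data push the unconstrained optimum outside the
  # PSD cone (tau3 ~ 0, tau2 < 0 makes tau1 tau3 - tau2^2 < 0)
  for (seed in 1:10) {
    rs <- withr::with_seed(seed, {
      g <- rbinom(800, 2, 0.4)
      residual_set(rnorm(800, 0, sqrt(3 - g)), g)
    })
    chi2 <- fit_chisq_regression(rs)
    vc <- fit_variance_component(rs)
    expect_lte(vc$lrt, chi2$lrt + 1e-8)
    expect_gte(vc$loglik_alt, vc$loglik_null - 1e-8)
    # constrained estimate satisfies PSD
    expect_true(vqtlscan:::is_psd_tau(c(vc$tau$tau1, vc$tau$tau2,
                                        vc$tau$tau3), tol = 1e-6))
  }
})

test_that("mixture p-value is the average of the two chi-squared survivals", {
  expect_identical(mixture_pvalue(0), 1)
  # 0.5 * 0.0500 + 0.5 * exp(-1.9205)
  expect_lt(abs(mixture_pvalue(3.841) - 0.0982), 1e-4)
  q <- seq(0.01, 30, length.out = 50)
  p <- mixture_pvalue(q)
  expect_true(all(diff(p) < 0))                       # strictly decreasing
  expect_true(all(p >= pchisq(q, 1, lower.tail = FALSE)))
  expect_true(all(p <= pchisq(q, 2, lower.tail = FALSE)))
  expect_error(mixture_pvalue(-1), "nonnegative")
})

test_that("pseudo-R2 is the likelihood-ratio variance-explained measure", {
  expect_identical(pseudo_r2(0, 100), 0)
  expect_equal(pseudo_r2(10, 1000), 1 - exp(-0.01))
  expect_lt(abs(pseudo_r2(10, 1000) - 0.00995), 1e-6)
  lrt <- seq(0, 50, by = 5)
  expect_true(all(diff(pseudo_r2(lrt, 500)) > 0))     # monotone in lrt
})

test_that("Brown-Forsythe test matches the by-hand ANOVA and stats::anova", {
  # identical value multisets across groups: no between-group signal
  rs <- residual_set(c(1, 2, 3, 1, 2, 3), c(0, 0, 0, 1, 1, 1))
  lv <- levene_bf(rs, hard_calls = rs$genotype)
  expect_equal(lv$statistic, 0)
  expect_equal(lv$p_het, 1)

  # hand-worked: A = {0,0,2,2}, B = {0,0,0,4}; medians 1 and 0;
  # z_A = {1,1,1,1}, z_B = {0,0,0,4}; SSB = 0, so F = 0
  rs <- residual_set(c(0, 0, 2, 2, 0, 0, 0, 4), rep(c(0, 1), each = 4))
  lv <- levene_bf(rs, hard_calls = rs$genotype)
  expect_equal(lv$statistic, 0)
  expect_equal(lv$p_het, 1)

  # independent oracle on seeded data: one-way ANOVA of the
  # median-centred absolute deviations via lm/anova
  rs <- make_het_resid(600, tau = c(1, 0.1, 0.5), seed = 31)
  hc <- rs$genotype
  lv <- levene_bf(rs)
  z <- abs(rs$residuals - ave(rs$residuals, hc, FUN = median))
  a <- anova(lm(z ~ factor(hc)))
  expect_equal(lv$statistic, a$`F value`[1], tolerance = 1e-10)
  expect_equal(lv$p_het, a$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(lv$df1, a$Df[1])
  expect_equal(lv$df2, a$Df[2])

  # small groups are dropped; fewer than two usable groups is an error
  rs <- residual_set(c(1, 2, 3, 9), c(0, 0, 0, 2))
  expect_error(levene_bf(rs, hard_calls = rs$genotype), "groups")
})
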