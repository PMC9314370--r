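---
title: "Variance-QTL methods: models, tests and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-QTL methods: models, tests and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vqtlscan)
```

## The problem

A standard GWAS asks whether the mean of a quantitative trait differs
across the genotypes of a variant. A variance QTL (vQTL) analysis asks
whether the *variance* does. Genotype-dependent trait variance arises
when the per-allele effect of a variant is not constant across
individuals — for example because unmeasured environmental factors or
other loci modulate it — so vQTL scans are a way to screen for
gene-environment and gene-gene interaction without measuring the
modulating factors. `vqtlscan` implements the model family, the four
tests, the genome-scan driver and the simulation machinery needed to run
such an analysis on dosage or hard-call genotype data at biobank scale.

## The model

Write the trait for one individual as

$$y = \sum_i \beta_i^{C} X_i + \beta^{G} G + \gamma_1 + \gamma_2 G,$$

where the $X_i$ are covariates, $G \in [0,2]$ is the additive genotype
(dosage), and $(\gamma_1, \gamma_2)$ is a zero-mean bivariate-normal
random pair: $\gamma_1$ collects the residual error together with all
genotype-independent effects of the unmeasured modulators, $\gamma_2$
their genotype-*dependent* (interaction) part. With
$\mathrm{cov}(\gamma_1, \gamma_2) = \begin{pmatrix} \tau_1 & \tau_2 \\
\tau_2 & \tau_3 \end{pmatrix}$, the conditional trait variance is
quadratic in the genotype:

$$v(G) = \tau_1 + 2\tau_2 G + \tau_3 G^2.$$

$\tau_1$ (trait units squared) is the baseline variance — the residual
error is absorbed into it and is not separately identifiable; $\tau_3$
is the variance of the per-allele effect; $\tau_2$ their covariance. The
null hypothesis of no variance heteroscedasticity is
$H_0\!: \tau_2 = \tau_3 = 0$.

## The four tests

All four tests share the same mean model (OLS of the trait on covariates
plus genotype, `fit_mean_model()`, which also reports the standard-GWAS
main effect) and differ in how they treat the variance law.

**Quadratic Breusch–Pagan regression** (`fit_ols_squared()`). The
squared residual is regressed on $(1, 2G, G^2)$, so the OLS coefficients
estimate $(\tau_1, \tau_2, \tau_3)$ directly, with no constraint and no
distributional assumption on $(\gamma_1,\gamma_2)$. The joint test of
$\tau_2 = \tau_3 = 0$ uses the Gaussian likelihood-ratio statistic
$n\log(\mathrm{RSS}_0/\mathrm{RSS}_1)$ on $\chi^2_2$.

**Chi-square regression** (`fit_chisq_regression()`). Because a squared
residual is a scaled $\chi^2_1$ variable — equivalently gamma with shape
$\tfrac12$ and scale $2v(G)$ — modelling $\hat e^2 = v(G)\,\chi^2_1$ and
maximising the exact likelihood is the efficient unconstrained version
of the same idea. Its log-likelihood is *identical* to the normal
likelihood of the variance-component model below (the package evaluates
both routes and tests their equality), and the LRT is again $\chi^2_2$.

**Variance-component model** (`fit_variance_component()`). The same
likelihood, but with $(\tau_1\ \tau_2; \tau_2\ \tau_3)$ constrained to
the positive-semidefinite cone, as befits a covariance matrix. Under
$H_0$ the parameter lies on the boundary of that cone, and the LRT
follows the 0.5:0.5 mixture of $\chi^2_1$ and $\chi^2_2$
(`mixture_pvalue()`). This is the default scan method: it has the same
power as the mixed model at a fraction of the cost.

**Linear mixed model** (`fit_lmm()`). Joint ML of fixed effects and
variance parameters, rather than conditioning on OLS residuals. For
fixed $\tau$ the fixed effects are weighted least squares with weights
$1/v(g_i)$; the two blocks are alternated until the joint likelihood is
stationary. Its LRT is compared to the same boundary mixture. In
practice the statistic is almost identical to the variance-component
one because ML fixed-effect estimates are robust to misspecification of
the covariance structure; the test suite checks agreement to better
than 1% relative on strongly heteroscedastic data.

A nonparametric comparison, the Levene/Brown–Forsythe test
(`levene_bf()`), is provided for hard-called genotypes: one-way ANOVA of
the absolute deviations of residuals from their genotype-group medians.

Effect sizes are reported as the likelihood-ratio pseudo-R²,
$1 - \exp(-\mathrm{LRT}/n)$ (`pseudo_r2()`); the reference for this form
is the Cox–Snell/Magee statistic, assumed here because the measure is
conventionally defined this way for LRT-based scans. The main-effect R²
is the partial R² of the genotype after covariates — the usual GWAS
convention; no other definition was stated for the scan output.

## Numerical choices

* **Optimisation.** Unconstrained fits use Newton–Raphson with the
  analytic gradient and Hessian of the variance likelihood, step-halving
  (up to 20 halvings) on any non-increase, a Fisher-scoring step
  whenever the Hessian is not negative definite, and convergence when
  the log-likelihood changes by less than 1e-8 (at most 50 iterations).
* **PSD constraint.** Enforced only when the unconstrained optimum
  leaves the cone, via the Cholesky parameterisation
  $(\tau_1\ \tau_2;\tau_2\ \tau_3) = LL^\top$; Newton–Raphson in the
  Cholesky parameters (chain-rule derivatives), with a guarded
  Nelder–Mead polish if it stalls. Boundary optima are reported with
  `converged = TRUE`.
* **Starting values.** Always the quadratic Breusch–Pagan estimates;
  infeasible starts (some $v(g) \le 0$) are repaired by inflating
  $\tau_1$ until $\min v(g) \ge 10^{-8}\,\overline{\hat e^2}$.
* **Degenerate inputs.** Monomorphic variants and exact-fit (zero
  residual variance) traits raise explicit errors in the fitting
  functions and are skipped with a logged reason by the scan driver.
  Genotypes with fewer than three distinct values make $G$ and $G^2$
  collinear and are rejected. LRTs that come out slightly negative by
  round-off are clamped at 0.
* **Hard calls.** Probability triplets are called by arg-max with ties
  broken toward the smaller genotype; dosages go to the nearest integer
  with half-way values also rounded down, so calls are deterministic.
* **P-values.** The main-effect p uses the $t$ reference with $n-p$
  df — indistinguishable from the normal reference at biobank $n$ and
  exact at the small $n$ used in tests.

## Phenotype preparation and filters

Blood-pressure traits follow the standard epidemiological pipeline:
SBP/DBP are averaged over repeated measurements; medicated individuals
get +15 mm Hg (SBP) and +10 mm Hg (DBP); pulse pressure is the
difference of the *adjusted* SBP and DBP (a net +5 mm Hg for medicated
samples — the adjustment order is a package choice, as is the natural
log applied to PP, which is right-skewed). Samples with missing traits
or covariates are dropped first; then, in a single pass (no iterative
re-screening), samples whose trait or BMI lies 5 or more sample SDs
from the sample mean are removed. Variant filters are strict
inequalities: MAF > 0.01 and info score > 0.9 by default; variants
without an info score pass that filter. Missing genotypes are handled
per-variant complete-case at test time, with `n` reported per record.

## What the simulator emulates — and what it does not

`simulation_spec()` states the generative world once:

* a systolic-blood-pressure-like trait,
  `86.5 + 5.65 sex + 0.00827 age² + 0.909 BMI + 0.0647 PC4 + 0.0349 PC9`
  plus background SNPs and N(0, 18.44²) error;
* covariates: sex ~ Bernoulli(0.46), age ~ U(40, 69) (the cohort
  recruitment range), BMI ~ N(27, 4.8²) truncated positive, 10 standard
  normal PCs — plumbing distributions, chosen as typical cohort values,
  not estimates;
* 54 background SNPs with constant effects; their (maf, beta) values
  are placeholder draws from the spec seed, since the real panel is
  literature-specific — they contribute homoscedastic mean structure
  only;
* one focal SNP whose per-allele effect is drawn i.i.d. per individual,
  $b_j \sim N(-0.475, \sigma^2)$, which induces exactly
  $\tau_3 = \sigma^2$, $\tau_2 = 0$. (A per-replicate constant draw
  would induce *no* within-replicate heteroscedasticity, so the
  per-individual reading is the one consistent with the variance law.)

Defaults are desk-scale (n = 10 000, 300 replicates, α = 0.05) so the
calibration and power studies run in minutes on one CPU;
`paper_scale = TRUE` restores the biobank-scale configuration
(n = 396 387, 1000 replicates, α = 5e-8). Genotypes and covariates are
held fixed across replicates — as when real cohort data are reused —
and every replicate draws its own error and random-effect stream from a
counter-derived seed, so any replicate is reproducible in isolation.

The simulator does **not** emulate linkage disequilibrium between SNPs,
dosage uncertainty, relatedness, or population structure beyond
independent PCs. A green calibration/power test therefore establishes
correct null behaviour and method ordering for independent HWE
genotypes with normal errors; it does not certify behaviour under LD or
non-normal traits (for skewed traits, transform first, as done for PP).

Two study-design choices deserve a note. The parameter-recovery check
(mean $\hat\tau_3$ within 10% of the truth, $\hat\tau_2$ within ±0.1 of
0 over 100 replicates at n = 50 000) runs in a unit-error generic-trait
world: a Fisher-information calculation shows that at blood-pressure
scale ($\tau_1 \approx 340$) the Monte-Carlo SD of $\hat\tau_2$ is ~1.7
per replicate, so the ±0.1 band could never be met — or missed —
informatively there; with unit error the band is a genuine bias check.
Similarly, the mixed-model/variance-component agreement check uses a
strong-effect generic world so the LRTs are large and "relative
difference" is well defined. Both choices were made from the power
analysis before the checks were run, and the thresholds were not
revisited afterwards.

## Known limitations

* The boundary mixture weights 0.5:0.5 are asserted, following the
  standard result for a variance component on a cone boundary; the
  package does not re-derive cone-specific weights for the joint
  two-parameter boundary. Null calibration is verified empirically
  instead.
* The regression tests are slightly anti-conservative at small n
  (the $\chi^2_2$ reference for the Gaussian LRT has O(1/n) error);
  at the scales the scan targets this is negligible.
* Meta-analysis of $\hat\tau$ across cohorts, LD clumping of scan hits,
  eQTL/sQTL annotation and BGEN parsing are out of scope.
* REML variants, sandwich-variance tests and joint mean-dispersion GLMs
  are deliberately not implemented; the scan's methods are the four
  tests above plus the Levene comparison.

## A minimal session

```{r example, eval = FALSE}
set.seed(1)
n <- 5000
g <- simulate_genotypes(n, maf = 0.3)
x <- rnorm(n)
b <- rnorm(n, -0.4, 1)                     # per-individual allele effect
y <- 120 + 0.5 * x + b * g + rnorm(n, 0, 2)

fit <- vqtl_fit(y, g, cbind(1, x), method = "all")
summary(fit)
plot(fit)                                  # squared residuals + v(G)
```

For file-based scans use `read_genotype_matrix()`,
`read_phenotype_table()` and `run_scan()`, or the installed `heter`
command-line tool (`exec/heter`): `heter scan`, `heter sim null`,
`heter sim power`.
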