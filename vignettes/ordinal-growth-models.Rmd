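---
title: "Multilevel ordinal growth models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel ordinal growth models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordgrowth)
```

## The model

`ordgrowth` fits two-level cumulative-logit growth models for longitudinal
ordinal outcomes. With stages $Y_{ti} \in \{1, \dots, K\}$ (1 = best) at
visit $t$ of subject $i$,

$$\operatorname{logit} P(Y_{ti} \le k) \;=\; \delta^{(k)}
  + \mathbf{x}^{*\prime}_{ti}\,\boldsymbol\beta_c^{(k)}
  + \mathbf{x}^{\prime}_{ti}\,\boldsymbol\beta
  + u_{0i} + u_{1i}\,t, \qquad k = 1,\dots,K-1,$$

with thresholds $\delta^{(1)} < \dots < \delta^{(K-1)}$ and
$(u_{0i}, u_{1i}) \sim N(\mathbf 0, D)$. Covariates in $\mathbf x$ act
proportionally — one coefficient across all cumulative logits — while
covariates in $\mathbf x^*$ get one coefficient per logit (non-proportional
odds, NPO). The proportional-odds (PO) model is the special case
$\boldsymbol\beta_c^{(1)} = \dots = \boldsymbol\beta_c^{(K-1)}$, so the two
are nested and a likelihood-ratio test of proportionality is available with
$(K-2)$ degrees of freedom per freed covariate column
(`lr_proportionality_test()`).

Under this sign convention a positive coefficient raises every cumulative
probability, i.e. shifts mass toward low-numbered (better) categories. The
assumptions worth keeping in mind: visits are conditionally independent
given the random effects; the random effects are Gaussian on the latent
logit scale; covariates are treated as exogenous. The last point matters for
treatment indicators that respond to the outcome history (see the generator
section).

### Parameterization

Internally both estimators work on an unconstrained vector: the first
threshold plus log-increments (ordering holds by construction), plain
coefficients, and the random-effects covariance as
$(\log\sigma_0, \log\sigma_1, \operatorname{atanh}\rho)$, which keeps $D$
positive definite and the correlation in $(-1, 1)$. Under NPO the cumulative
logits of a covariate pattern can cross; any parameter vector that makes
them non-monotone at an *observed* pattern receives likelihood $-\infty$
(soft rejection) rather than a reparameterized constraint — the standard
practice for partial proportional-odds fitting, which keeps the parameter
space simple. Because the random effect shifts all logits of a row equally,
validity is checked once per row from the fixed part alone.

### Marginal likelihood: adaptive Gauss–Hermite quadrature

The subject-level likelihood integrates the bivariate random effect out.
Per subject, the integrand is re-centred at its conditional mode (Newton
iterations with analytic gradient and Hessian in $u$) and re-scaled by the
Laplace curvature; a tensor Gauss–Hermite grid of `quad_order` nodes per
dimension is then applied to the standardized effect. A zero slope variance
collapses to one-dimensional quadrature; $D = 0$ reduces to the conditional
likelihood at $u = 0$. The default order is 9 per dimension; the validation
experiments use order 5, which changes coefficient estimates by only a few
hundredths on the logit scale at the default generating values.

One numerical characteristic is worth stating plainly: at an intercept
variance as large as the default 12.21, the integrand of a subject with one
or two visits is strongly non-Gaussian (a wide sigmoid plateau times the
prior), and order-7 quadrature retains an intrinsic per-subject error of a
few $10^{-4}$ on the log scale. We verified against exact one-dimensional
integration that this is a property of low-order Gauss–Hermite rules on
such integrands, not of the adaptation (neither moment matching nor grid
inflation improves it uniformly). The test suite measures this gap
explicitly; agreement with 200,000-draw Monte-Carlo integration is well
within one Monte-Carlo standard error throughout.

### Maximum likelihood

`ogm()` maximizes the marginal likelihood with `nlminb()` from a
deterministic start: thresholds at the logits of the marginal cumulative
frequencies, zero coefficients, $D = \mathrm{diag}(1, 0.01)$. Standard
errors come from the inverse numerical Hessian, mapped to the natural scale
(thresholds, coefficients, variance components) by a finite-difference
delta method; intervals are Wald, exponentiated for odds-ratio reporting.
When a model with category-specific effects is fitted after its
proportional counterpart, passing the PO fit as `init` starts the NPO
optimization from the restricted optimum; this guarantees the LR statistic
is non-negative up to optimizer tolerance and is how the package's own
experiments fit nested pairs.

### Bayesian estimation and DIC

`ogm_mcmc()` runs adaptive random-walk Metropolis on the same unconstrained
vector, targeting the quadrature marginal likelihood plus the prior, so the
random effects never enter the chain. Default priors: normal with standard
deviation 10 on thresholds-increments and coefficients, half-normal with
scale 5 on both random-effect standard deviations (with the log-scale
Jacobian), uniform on the correlation (with the $\operatorname{atanh}$
Jacobian). The proposal covariance is learned from the chain history during
burn-in with a global scale tuned toward 30% acceptance, then frozen.
Deviance summaries follow the standard definitions:
$\bar D$ is the mean posterior deviance, $p_D = \bar D - D(\bar\theta)$ at
the posterior mean, $\mathrm{DIC} = \bar D + p_D$. A chain whose acceptance
rate leaves $[0.1, 0.6]$ is flagged and `compare_dic()` declines to declare
a preference.

### Intraclass correlation

On the latent scale the level-1 variance of the logistic link is fixed at
$\pi^2/3$, so `icc_latent()` returns
$\sigma^2_{v0} / (\sigma^2_{v0} + \pi^2/3)$. At $\sigma^2_{v0} = \pi^2/3$
the ICC is exactly 0.5; at the default generating variance 12.21 it is
0.7877. Note this uses only the intercept variance; with a random slope the
latent between-subject share varies with time, and the reported scalar is
the $t = 0$ value.

## WHO staging and descriptives

`who_stage()` maps CD4 counts to the four WHO immunological bands with a
closed-left convention — $[500, \infty)$, $[350, 500)$, $[200, 350)$,
$[0, 200)$ — so the boundary counts 200, 350 and 500 land in the band whose
printed range starts there ("350–499", "≥ 500"). `baseline_table()` rounds
percentages half-up to one decimal with the per-variable non-missing count
as denominator, and uses type-7 (linear interpolation) quantiles for the
median and IQR. `correlation_significance()` bands two-sided p-values from
the $t$ approximation at 0.05 / 0.01 / 0.001; zero-variance columns are
reported as missing with a warning record rather than an error.

## Factor reduction

Clinical panels are reduced by principal-component extraction from the
correlation matrix, retaining factors with eigenvalue strictly greater
than 1 (values within $10^{-10}$ of 1 are not retained; if nothing
qualifies the first factor is kept so the solution is non-empty). The
package implements varimax itself as iterated pairwise planar rotations
with Kaiser row normalization, a tolerance on the criterion gain and an
iteration cap, because the rotation contract here includes a convergence
flag and deterministic sign/ordering conventions: each factor's
largest-magnitude loading is made positive and factors are ordered by
explained variance. On panels with two equally strong blocks the
initial loadings sit near a symmetric saddle of the varimax criterion
where SVD-based implementations can stall; the pairwise algorithm walks
off it, and the test suite checks that the result is a fixed point of
`stats::varimax` and scores at least as high on the criterion. Loading
strengths are banded at 0.4 and 0.6 (weak / moderate / strong). Factor
scores use the regression method — standardized data times
$R^{-1}\Lambda$ — standardizing with the extraction sample's means and
standard deviations, so new observations can be scored consistently.
Maximum-likelihood extraction and oblique rotations are out of scope.

## The synthetic cohort generator

The generator exists so that every downstream stage has inputs with known
truth. Its defaults describe the study conditions the package targets:

* **219 subjects**, followed up to **13.13 years**. Each subject gets a
  follow-up horizon drawn exponentially with median **2.12 years**
  (truncated at the maximum) and a baseline visit at $t = 0$ plus a
  homogeneous Poisson visit stream at 3 visits/year over that horizon. A
  single truncated Poisson stream cannot give both a 2-year median and a
  13-year maximum of last-visit times, hence the per-subject horizon.
* **Outcome**: thresholds $\log(0.02, 19.87, 24.51)$; random-effects
  covariance $D = \begin{pmatrix} 12.21 & -0.36 \\ -0.36 & 0.02
  \end{pmatrix}$; category-specific effects for time
  ($e^{\beta} = 0.55, 0.66, 1.76$ per year) and cART
  ($1.42, 1.27, 1.28$); shared effects for viral load ($0.56$ per
  log$_{10}$ copy) and the quality-of-life and clinical factor scores.
  Per-logit effects for *continuous* covariates at this threshold spacing
  would make the cumulative logits cross within the covariate's realistic
  range (the increment between the second and third thresholds is only
  0.21), so continuous covariates act proportionally at the middle logit's
  value — a binary or time-like covariate is the only kind that can carry
  the full per-logit pattern without violating monotonicity.
* **Covariates** are centered at their generating means before entering the
  linear predictor (viral load at 4.46 log copies, QoL domains at 14 on a
  4–20 scale), so the thresholds keep their meaning at a typical pattern.
* **cART** initiates at the first visit *after* a visit with stage ≥ 2
  (CD4 below 500): initiation cannot precede observation, and `on_cart`
  never reverts. Phases follow time — II before 3 months, III to 12
  months, IV after — and become V on treatment.
* **CD4 counts** are drawn uniformly within the observed stage's band,
  capped at 1200 (top) and 50 (bottom), so `who_stage()` round-trips.
* **Clinical panels** are generated from the latent factor scores through a
  block loading matrix (electrolyte, red-cell-index and mononuclear blocks)
  plus independent noise, giving the factor stage real structure to
  recover.
* All randomness flows from one seed; visit- and outcome-level draws use
  per-subject substreams, so a trajectory is reproducible regardless of
  cohort ordering, and identical configuration plus seed gives
  byte-identical output.

What the generator deliberately does **not** emulate: viral dynamics or
seroconversion biology, informative dropout or death (censoring is
non-informative by construction), measurement error in CD4, and visit
schedules that react to disease state. Passing tests on generated data
therefore demonstrate correctness of the estimators under the stated model,
not robustness to those real-data features. One consequence of the
treatment rule deserves emphasis: because cART initiation depends on past
*outcomes*, which depend on the random effects, `on_cart` is not exogenous
in the generated cohort, and fitted treatment effects absorb some of that
feedback (visible as cART odds ratios above their generating values in the
README example). The estimation-validation experiments therefore use
exogenous covariates only, with the treatment rule disabled.

## Validation experiments and problem sizes

The test suite fixes these designs (chosen once as realistic for the
methods, with runtimes suitable for routine re-running):

* **Quadrature oracle**: 10 default-config subjects; adaptive quadrature
  versus 200,000-draw Monte-Carlo integration, per subject, within three
  Monte-Carlo standard errors; order 7 versus 15 gap measured and asserted
  at $10^{-4}$ (see the numerical note above for why that figure is not
  attainable at intercept variance 12.21 — the assertion documents the gap).
* **Parameter recovery**: 100 replicates of 300 subjects, fixed 5-year
  horizon at 1 visit/year (about 6 visits each), thresholds and $D$ at the
  default generating values, three exogenous covariates (time, a mean-zero
  continuous visit covariate, a balanced binary subject covariate);
  quadrature order 5. Absolute bias below 0.1 on the logit scale for every
  threshold and coefficient; 95% Wald coverage within $[0.90, 0.99]$.
* **LR calibration**: 200 proportional-odds replicates of 100 subjects
  (random intercept, variance 4, wider threshold spacing so all categories
  are populated at this size); the NPO fit frees the balanced binary
  covariate (df = 2). Type-I error at $\alpha = 0.05$ within $[0.02,
  0.09]$; the statistic never below $-10^{-4}$.
* **Factor recovery**: two planted three-variable blocks with loadings 0.9
  and unit total variance at $n = 5000$; rotated loadings within 0.05 of
  the planted values; communalities preserved to $10^{-8}$.
* **Determinism**: the full pipeline run twice at one configuration and
  seed produces byte-identical numeric artifacts.

## Known limitations

Only the logit link is provided (no probit/cauchit/cloglog); models are
two-level (no third level); missing data must be handled upstream;
time-by-covariate interactions are built as proportional columns unless the
derived column is explicitly freed; Wald intervals for variance components
are delta-method approximations and can be poor near zero variance — the
MCMC credible intervals are preferable there; and DIC from short chains is
noisy, so chain lengths in the pipeline defaults are a compromise for
routine use, not a recommendation for final inference.
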