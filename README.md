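# ordgrowth

Multilevel ordinal growth models for longitudinal immunological staging.

## The problem

CD4 cell counts of HIV-infected patients are routinely collapsed into the
four WHO immunological stages — normal (≥ 500 cells/mm³), mild (350–499),
advanced (200–349) and severe (< 200) — and followed over years of repeated
visits. The outcome is ordinal, floor- and ceiling-bounded, and visits are
nested within patients, so linear mixed models on the raw counts are a poor
fit. `ordgrowth` is for biostatisticians and epidemiologists who want to
model such trajectories directly on the ordinal scale, decide whether
covariate effects may be pooled across the outcome's cumulative splits, and
quantify between-patient heterogeneity.

## The model

For visit *t* of subject *i* with stage `Y_ti ∈ {1, …, K}` (1 = best), the
two-level cumulative-logit growth model is

    logit P(Y_ti ≤ k) = δ⁽ᵏ⁾ + x*'_ti β_c⁽ᵏ⁾ + x'_ti β + u_0i + u_1i · t,
    (u_0i, u_1i) ~ N(0, D),     k = 1, …, K − 1,

with strictly increasing thresholds δ⁽¹⁾ < … < δ⁽ᴷ⁻¹⁾. Covariates in `x`
act **proportionally** (one coefficient across all K − 1 cumulative logits);
covariates in `x*` are **category-specific** (non-proportional odds, NPO),
one coefficient per logit. A positive coefficient raises P(Y ≤ k): better
immunological states. The correlated random intercept and time slope give
each subject its own baseline level and recovery rate on the latent scale.

The package provides:

* maximum likelihood with the random effects integrated out by **adaptive
  Gauss–Hermite quadrature** (`ogm()`), with Wald intervals from the
  numerical Hessian;
* **adaptive random-walk Metropolis** sampling of the same marginal
  posterior (`ogm_mcmc()`), reporting `dbar`, `pD` and the **DIC**;
* the **likelihood-ratio test of proportional odds**
  (`lr_proportionality_test()`), df = (K − 2) per freed covariate column;
* the latent-scale **intraclass correlation** `icc_latent()` =
  σ²_v0 / (σ²_v0 + π²/3);
* WHO CD4 staging (`who_stage()`), baseline descriptives
  (`baseline_table()`), correlation screening with significance bands
  (`correlation_significance()`);
* exploratory **factor reduction** of clinical panels: principal-component
  extraction, Kaiser retention, in-package varimax rotation, loading
  strength bands and regression factor scores (`reduce_panel()`);
* a **synthetic longitudinal cohort generator** (`simulate_cohort()`) whose
  defaults emulate a 219-subject seroconversion cohort followed up to 13.13
  years, with cART initiated once CD4 falls below 500, and clinical panels
  with planted factor structure — so every stage of the analysis is testable
  without access to patient data;
* an end-to-end pipeline (`run_pipeline()`) writing cohort, descriptives,
  factor solution, both fits, LR test, DIC report and a manifest.

## Worked example

```r
library(ordgrowth)

cohort <- simulate_cohort(sim_config(n_subjects = 219, seed = 1))

spec_po  <- model_spec(shared = c("time", "log_vl", "on_cart"), random = "slope")
spec_npo <- model_spec(shared = "log_vl", npo = c("time", "on_cart"), random = "slope")

fit_po  <- ogm(cohort, spec_po,  quad_order = 5)
fit_npo <- ogm(cohort, spec_npo, quad_order = 5, init = fit_po)

lr_proportionality_test(fit_po, fit_npo)
#> Likelihood-ratio test of the proportional-odds assumption
#>   chi-squared = 304.46, df = 4, p = 1.185e-64
#>   REJECT proportional odds at alpha = 0.05

odds_ratio_table(fit_npo)
#> Exp(beta) (95% CI) per cumulative logit
#>              logit 1               logit 2               logit 3
#> log_vl       0.52 (0.45, 0.60)***  0.52 (0.45, 0.60)***  0.52 (0.45, 0.60)***
#> time         0.60 (0.49, 0.74)***  0.70 (0.64, 0.76)***  1.59 (1.36, 1.85)***
#> on_cart      2.61 (1.42, 4.81)**   1.84 (1.08, 3.14)*    2.19 (1.25, 3.82)**
#> Random components / diagnostics
#>   var_u0                  12.7124 ***
#>   cov_u0u1                -0.4213 ns
#>   var_u1                   0.0240 ns
#>   icc_latent               0.7944
#>   minus2loglik          3099.1508
```

Reading the output: the generator plants category-specific time effects
(odds ratios 0.55 / 0.66 / 1.76 per year across the three cumulative logits)
and a shared viral-load effect (OR 0.56 per log₁₀ copy); the fit recovers
them (0.60 / 0.70 / 1.59 and 0.52), the LR test firmly rejects pooling the
time and cART effects across logits, and the fitted random components
(intercept variance 12.7, slope variance 0.024) reproduce the planted
heterogeneity, giving a latent-scale ICC of 0.79 — about 79% of latent
variance lies between subjects.

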