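---
title: "Methods: mapping QLQ-C30 scores to EQ-5D-3L utilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping QLQ-C30 scores to EQ-5D-3L utilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical model, the estimation choices, the
synthetic-data generator, and the numerical decisions behind `qlqmap`. It is a
methods document, not a tutorial; the README has the worked example.

## The mapping problem

Cancer trials usually collect the EORTC QLQ-C30, a cancer-specific
quality-of-life questionnaire summarised as fifteen 0–100 scales (global
health, five functional scales, nine symptom scales). Cost-effectiveness
models need preference-based utilities, most commonly EQ-5D-3L index values
under the UK time-trade-off tariff. When EQ-5D was not collected, a *mapping*
model predicts utility from the QLQ-C30 scales.

The UK EQ-5D-3L tariff gives the index a hard geometry that any sensible
mapping must respect:

- 243 health states (5 dimensions × 3 levels), of which 11111 scores exactly
  1 and 33333 scores −0.594;
- the best non-perfect states score 0.883, so the interval (0.883, 1) contains
  **no feasible value** — the distribution has a gap below a point mass at 1;
- observed utility distributions are left-skewed, multimodal, and spiked at 1.

A linear model ignores all three features. It over-predicts for the sickest
patients, under-predicts for the healthiest, and produces values inside the
infeasible gap. The package's core contribution is an adjusted limited
dependent variable mixture model (ALDVMM) that encodes the geometry directly,
plus two comparators (a linear random-effects model and an indirect
"response mapping" via ordered probits) and the diagnostics to tell them
apart.

## The ALDVMM likelihood

Let $\Psi_1 = 0.883$ (gap edge) and $\Psi_2 = -0.594$ (the floor). For
component $c$ with linear predictor $\mu_c = x^\top\beta_c$ and scale
$\sigma_c$, a latent normal $Y^* \sim N(\mu_c, \sigma_c^2)$ is censored to the
feasible set:

- $y = 1$ whenever $Y^* \ge \Psi_1$: contribution
  $1 - \Phi\!\left(\frac{\Psi_1 - \mu_c}{\sigma_c}\right)$;
- $y = \Psi_2$ whenever $Y^* \le \Psi_2$: contribution
  $\Phi\!\left(\frac{\Psi_2 - \mu_c}{\sigma_c}\right)$;
- otherwise $y = Y^*$: contribution
  $\frac{1}{\sigma_c}\phi\!\left(\frac{y - \mu_c}{\sigma_c}\right)$.

Mapping the whole upper tail to 1 reproduces both the point mass at full
health and the empty gap. Component membership is multinomial-logit on
$z = (1, \text{gh}, \text{gh}^2)$ where gh is global health / 100, with
component $K$ as the reference category:
$p_c(z) = \exp(z^\top\gamma_c) / \sum_k \exp(z^\top\gamma_k)$, $\gamma_K = 0$.
The observation likelihood is $\sum_c p_c(z)\, f_c(y \mid x)$.

The default design is an intercept, the fifteen scales divided by 100, and
age in decades; membership uses gh and gh². These are package choices — both
matrices are arguments and any design can be supplied.

### Parameterisation and scores

Scales are estimated as $\eta_c = \log\sigma_c$ (unconstrained). The packed
parameter vector is component-major: all $\beta$, then all $\eta$, then the
$K-1$ free $\gamma$ rows. The gradient is analytic throughout: the $\mu$ and
$\eta$ derivatives use Mills-ratio forms for the censored pieces, and the
membership derivative is $(W_c - p_c)\,z$ with $W_c$ the posterior
responsibility. Per-observation scores are retained because they feed the
cluster-robust covariance: with bread $H^{-1}$ from the final Hessian and meat
$\frac{G}{G-1}\sum_g s_g s_g^\top$ over cluster-summed scores $s_g$, the
reported standard errors are sandwich estimates clustered on patient.

### Numerical decisions

- **Degeneracy barrier.** Mixtures of censored normals can push a component's
  $\sigma$ to zero on a single interior point. The objective adds a smooth
  penalty $10^3 \max(0, \log(0.015) - \eta_c)^2$ below $\sigma = 0.015$, and
  solutions with any $\sigma < 5\times10^{-3}$ are rejected as degenerate.
  The barrier is inert at every legitimate optimum we fit (all shipped truths
  and all test fits have $\hat\sigma \ge 0.04$).
- **Overflow guards.** $\eta$ is clamped to $[-30, 5]$ inside the unpacker so
  BFGS line-search excursions cannot underflow $\exp(\eta)$ to zero; tail
  probabilities use `pnorm(log.p = TRUE)` and log-sum-exp mixing.
- **Multi-start.** `n_restarts` BFGS runs from seeded random starts (plus one
  deterministic start), `parscale` set from column scales so scale-0–100
  covariates and the intercept step comparably; the winner is polished until
  the gradient max-norm per observation falls below `1e-6` (up to three
  polishing rounds at `reltol 1e-14`).
- **Label order.** Components are relabelled by decreasing average posterior
  membership so replicate fits are comparable.

### Information criteria and prediction

`glance()` reports AIC $= 2k - 2\ell$, BIC $= k\log n - 2\ell$, and a
quasi-likelihood criterion QIC $= -2\ell + 2\,\mathrm{tr}(J V_{\text{robust}})$
with $J$ the observed information — the working-independence form, which
collapses to AIC when the robust and model-based covariances agree.

The predicted mean respects the censoring exactly:
$E[y] = \sum_c p_c\left[(1 - \Phi_u) \cdot 1 + \Phi_l \Psi_2 +
(\Phi_u - \Phi_l)\, m_c^{\text{trunc}}\right]$ with $m_c^{\text{trunc}}$ the
doubly-truncated normal mean. Note the contract: *expectations* lie in
$[-0.594, 1]$ and may fall inside the open gap (an average of mass at 1 and
mass at 0.883 must), while *simulated draws* are individually feasible and
never fall in (0.883, 1).

## Response mapping (indirect comparator)

Five independent ordered probits (`MASS::polr`, probit link) model the five
EQ-5D dimensions on the scales plus age and age²; design columns are
normalised to unit mean absolute value before fitting and coefficients and
covariance transformed back, which keeps the Hessian well-conditioned.
Cluster-robust covariances come from `sandwich::vcovCL`. If a sample never
exhibits a dimension's worst level the model degrades to a binary probit and
the missing cutpoint is pinned six probits above the identified one — the
level-3 probability is effectively zero, matching the data that caused the
fallback, and a warning is raised.

The expected utility is the exact 243-term sum
$E[U] = \sum_{\text{states}} \left(\prod_d P_d(\text{level})\right) U(\text{state})$
under cross-dimension independence. An optional Gaussian-copula layer
estimates residual correlation from generalised (latent) residuals and
replaces the product rule with seeded Monte-Carlo rectangle probabilities;
it is off by default because the independence version is deterministic and
the correlation refinement changes expected utilities by well under 0.01 at
the correlation levels the generator produces.

## Linear random-effects comparator

`lme4::lmer` (maximum likelihood) fits utility on the same design with a
patient random intercept; samples where every cluster is a singleton collapse
to OLS. Fixed-effect covariances are cluster-robust via a hand-coded GLS
sandwich (the exchangeable $V_i^{-1}$ applied through the Woodbury identity),
since no installed package provides that for `lmer` fixed effects.
Predictions are deliberately *not* clamped: producing infeasible values is
the comparator's documented failure mode and the diagnostics quantify it.

## Synthetic data generator

`make_synthetic_dataset()` is the package's test bed and demonstration data
source. Defaults describe a metastatic-breast-cancer-like panel: 602 patients,
visit counts from a shifted negative binomial (mean ≈ 6.3), age ~ N(53.6,
10.5²), 4.2% item missingness, and fifteen QLQ-C30 scales driven by a shared
severity factor (patient component weight $\sqrt{0.6}$, visit component
$\sqrt{0.4}$, loading 0.6, signs + for functional, − for symptom scales).
Scale marginals are winsorised normals whose latent mean/SD are solved at
generation time by moment-matching so the *post-clamping* mean and SD hit the
targets; an infeasible target (residual > 1e-4) is an error, not a silent
approximation.

Utilities come from a shipped four-component ALDVMM truth. Its constants were
calibrated by a constrained moment-match so that, at the default panel size, the membership-weighted
post-censoring component means and SDs reproduce the component summary table
the package documents (probabilities 0.221/0.321/0.169/0.289; means
0.672/0.824/0.474/0.778; SDs 0.070/0.242/0.371/0.126), the pooled
distribution has mean ≈ 0.715 with ≈ 22% of observations at full health,
and an all-best QLQ-C30 profile predicts above 0.9. Within-patient
correlation enters through a small patient random effect (SD 0.05) on the
latent scale. A second mode ("dimension_latent") generates EQ-5D responses
from the ordered-probit truth instead, for testing the response-mapping
estimator; its residuals share a Gaussian factor with correlation 0.25.

The generator reproduces the *shape* that motivates the mixture — spike at 1,
empty gap, left skew, severity-dependent variance — not any particular
patient population; it makes no claim of clinical realism beyond those
moments.

## Testing and reproducibility choices

Problem sizes in the test suite are the package's own choices, set to keep
the full suite within a CI budget while leaving honest statistical margins:
parameter-recovery checks use 20 replicates of n = 5000 for the
two-component mixture and 12 replicates for the ordered-probit and
random-effects recoveries, with 3-standard-error Monte-Carlo bands plus a
small absolute guard for finite-replicate noise. Likelihood values are
checked against quadrature oracles in which extreme tail masses are computed
by factoring out the boundary density, so the quadrature controls relative —
not absolute — error. `scripts/acceptance.R` recomputes the two headline
reference quantities (the 0.883 gap edge from full enumeration; the pooled
SD 0.0628 from the component summary table via the law of total variance)
against the installed package and writes them as JSON.

## Limitations

- The mixture likelihood is multimodal; the multi-start strategy is a
  heuristic, and `n_restarts` should be increased for K > 2 on small samples.
- Membership depends on global health only (by design); other drivers of
  component switching are absorbed into the component densities.
- The response mapping assumes cross-dimension independence by default;
  the copula layer is a stopgap, not a joint multilevel estimator.
- Standard errors are cluster-robust but the point estimates ignore the
  panel structure (pooled ML), which is consistent but not efficient.
- The generator's calibration targets marginal and component moments, not
  longitudinal trajectories; treat time-path analyses on synthetic data with
  caution.
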