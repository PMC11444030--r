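---
title: "Decomposing a sanitation intervention's effect on child diarrhea: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing a sanitation intervention's effect on child diarrhea: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtmediate)
```

## The scientific problem

A multi-component sanitation intervention — latrine upgrades, child feces
management tools, behavioral promotion — delivered in a cluster-randomized
trial reduced caregiver-reported diarrhea among children under five. Which
component did the work? `crtmediate` answers that question with causal
mediation analysis: it decomposes the intervention's total effect on diarrhea
prevalence into the part transmitted through each measured mediator (the
**average causal mediation effect**, ACME) and the remainder (the **average
direct effect**, ADE), both on the prevalence-difference scale.

For one mediator $M$, treatment $T \in \{0,1\}$ and binary outcome $Y$, the
counterfactual estimands are

$$\mathrm{ACME}(t) = E\left[Y(t, M(1)) - Y(t, M(0))\right], \qquad
  \mathrm{ADE}(t) = E\left[Y(1, M(t)) - Y(0, M(t))\right],$$

with the exact decomposition $\mathrm{ACME}(1) + \mathrm{ADE}(0) =
\mathrm{ACME}(0) + \mathrm{ADE}(1) = E[Y(1,M(1)) - Y(0,M(0))]$ (the total
effect). Reported averages weight the two conditional estimates by the arm
proportions. A negative ACME means the pathway was protective — the
intervention moved the mediator in a direction that lowered diarrhea
prevalence.

## The three-step pipeline

`run_full_analysis()` executes the procedure separately for monsoon and dry
seasons (the intervention's effect is seasonal, and `season_tools` derives
the monsoon window from daily rainfall as the span between the first and
last days whose 5-day rolling average rainfall is at least 10 mm):

1. **Mediator screen** (`step1_screen`). Each candidate mediator is
   regressed on treatment with block fixed effects: log-binomial for binary
   mediators (prevalence ratios), Poisson for counts (count ratios),
   proportional odds for ordinal mediators (a single cumulative odds ratio).
   Mediators with a treatment association at $\alpha = 0.05$ are retained.
2. **Adjusted outcome model** (`step2_fit`). Diarrhea is regressed on
   treatment, the mediator and prescreened covariates
   (`screen_covariates`, bivariate outcome association at $\alpha = 0.20$),
   again with block fixed effects.
3. **Counterfactual mediation** (`mediate_single` / `mediate_dependent`).
   Latrine-quality and feces-management mediators are assumed causally
   independent of other mediators and get the quasi-Bayesian estimator;
   latrine-use mediators are assumed downstream of latrine quality and get
   the structural-equation estimator with the significant latrine-quality
   mediators as upstream post-treatment confounders.

Row sets are computed once per mediator and season — season records,
complete cases on the outcome and retained covariates, non-missing mediator,
within the mediator's availability window — and reused across all three
steps, so every step sees the identical `n`. Mediators recorded only in some
rounds (e.g., latrine age in rounds 1–2) are screened on their available
rounds but excluded from step 3 by default, since their counterfactual
row set would not match the other mediators'; set
`analysis_config(include_partial_mediators = TRUE)` to override. No
multiple-testing correction is applied anywhere, matching the reporting
convention the pipeline emulates.

## Quasi-Bayesian estimator (`mediate_single`)

`n_sims` parameter vectors are drawn from a multivariate normal centred at
the (mediator-model, outcome-model) estimates with their **cluster-robust**
covariance, clustered on the study block. For each draw, counterfactual
mediator distributions under $T = 0$ and $T = 1$ are formed for every
observation and pushed through the outcome model to get expected potential
outcomes. Point estimates are means over draws, confidence intervals the
2.5/97.5 draw percentiles, and the two-sided p-value
$2\min\{\Pr(\hat\theta \le 0), \Pr(\hat\theta \ge 0)\}$ over draws.

Numerical choices that matter:

* **Exact mediator expectation.** For binary and ordinal mediators the
  expectation over the simulated mediator distribution is a finite sum, so
  it is computed exactly instead of drawing category realisations; count
  mediators are drawn Poisson, and gaussian (identity-link) mediators enter
  through their conditional mean. This changes no estimand — it replaces a
  Monte-Carlo average with its exact value — and makes the linear
  identity-link case reproduce the product-of-coefficients formula to
  machine precision, which the test suite asserts at $10^{-8}$.
* **Expected potential outcomes.** Potential outcomes are expected
  probabilities, not Bernoulli draws, again reducing Monte-Carlo noise
  without moving the estimand.
* **Decomposition identity.** Within every draw,
  $\mathrm{ACME}(1)+\mathrm{ADE}(0) = \mathrm{ACME}(0)+\mathrm{ADE}(1) =
  \text{total}$ holds exactly by construction; the acceptance suite asserts
  it at $10^{-12}$.
* Log-link fitted probabilities are clamped to $[0,1]$ inside a draw;
  identity-link values are left unclamped so linear-probability oracles stay
  exact.

## Post-treatment confounding (`mediate_dependent`)

Latrine-use behaviours sit downstream of latrine quality: randomization
improves quality ($W$), quality changes use ($M$), and quality also affects
diarrhea directly. Conditioning on $W$ in the standard estimator is wrong
($W$ is post-treatment); omitting it confounds the $M$–$Y$ relation. The
package follows the varying-coefficient linear structural-equation approach:

$$M = a_0 + a_1 T + a_2' W + a_3' X + \varepsilon_M, \qquad
  Y = b_0 + b_1 T + (b_2 + b_3 T) M + b_4' W + b_5' X + \varepsilon_Y,$$

with $b_3$ the varying (treatment-modified) mediator coefficient. Because
$W$ is itself affected by treatment, the counterfactual mediator shift must
include the $T \to W \to M$ path and the direct effect the $T \to W \to Y$
path:

$$\Delta_M = a_1 + a_2' \Delta_W, \qquad
  \mathrm{ACME}(t) = (b_2 + b_3 t)\,\Delta_M, \qquad
  \mathrm{ADE}(t) = b_1 + b_4' \Delta_W + b_3\,E[M(t)],$$

where $\Delta_W$ is the arm difference in the confounder means and $E[M(0)]$
is evaluated at the control-arm confounder distribution and the sample
covariate means. Both equations are linear-probability models even for the
binary outcome: the method is defined for linear structural equations and
effects are reported as prevalence differences. Uncertainty comes from a
nonparametric bootstrap that resamples whole study blocks, keeping each
matched treatment-control pair together; resamples containing a single arm
are redrawn and counted. Block fixed effects are not added to the two
equations — block structure is honoured by the block-level resampling
instead.

In simulation (200 replicates of the packaged post-treatment-confounding
world), this estimator's absolute bias for the oracle ACME is an order of
magnitude smaller than the naive single-mediator estimator's; the
acceptance suite re-runs that comparison.

## Regression engines and clustered variance

* **Log-binomial with modified-Poisson fallback.** The fallback triggers on
  optimizer non-convergence *or* any fitted probability $\ge 1 - 10^{-8}$
  (the boundary failure mode); the refit is Poisson with log link on the
  binary outcome, whose robust variance restores valid inference and whose
  exponentiated coefficients remain prevalence ratios. Saturated two-group
  fits of either family reproduce the crude ratio exactly — the oracle for
  the screening-table worked examples.
* **Cluster-robust sandwich (CR1).** Scores are summed within cluster and
  the meat is scaled by $G/(G-1)$. Scores for proportional-odds fits are
  derived analytically (per-observation gradients in $(\beta, \zeta)$). A
  two-level "ordinal" outcome is fit as binary logistic regression and
  re-expressed in proportional-odds parameterisation, preserving the
  2-levels-equals-logistic identity.
* **Clustering unit.** The mediation step clusters parameter covariance on
  the **study block**. For the block-adjusted screening models the package
  also defaults to block-level clustering, a deliberate choice: with exactly
  two clusters per matched block, block fixed effects absorb half the
  between-cluster variation and a sub-block CR1 sandwich is severely
  anti-conservative (measured type-I error ≈ 0.20 at nominal 0.05 in the
  packaged null world, versus ≈ 0.07 when clustering on block). The unit is
  configurable (`cluster_var`).
* Degenerate outcomes (no variation) and aliased fits return a
  non-converged `crt_fit` with a reason, so screening loops can record and
  skip rather than crash.

## Season detection

The rolling mean is **trailing** (the window ends on the labelled day) by
default and switchable to centred; the defining phrase "between the first
and last days" makes both window boundaries inclusive. Multiple rain
stations are averaged day-wise before detection. Gaps in a year's series are
an error unless `gap_tolerance` allows linear interpolation. Reproducing the
particular published window dates would require the external meteorological
series and is out of scope; the tests instead verify agreement with a
brute-force enumeration oracle on constructed series.

## Polychoric correlations

Mediator overlap is audited with Pearson correlations for binary–binary
pairs and polychoric correlations for any pair involving an ordinal
variable. The polychoric estimator is the standard two-step: thresholds from
the inverse-normal of cumulative marginals, then the latent bivariate-normal
correlation maximising the cell likelihood over $(-0.999, 0.999)$. The
reported SE is curvature-based on the profile likelihood in $\rho$ and
ignores threshold uncertainty, as is conventional for the two-step
estimator. Zero-margin rows/columns are collapsed with a warning; pairs with
$|r| > 0.5$ are flagged. Perfectly concordant tables run to the 0.999 search
boundary by design.

## The synthetic trial generator

`synth_config()` states a world emulating the target trial's structure: 50
geographically matched blocks, one sanitation and one control cluster per
block (assignment exactly balanced within block, the treated label
randomized), 7 compounds per cluster with one index child each, and 8
survey rounds alternating mid-January/mid-July so both seasons are
populated, with monsoon windows of April 1 – September 30. Covariates are
child age in months (baseline uniform 0–30, aged by calendar time), sex,
and a compound-level standard-normal wealth score. Missingness is MCAR only
(the emulated analysis is complete-case), defaulting to 0.2% on the outcome.

The default mediator set spans the three categories with intercepts and
treatment paths chosen so arm-specific prevalences match the published
step-one table to first order: a hygienic-latrine indicator (76% control →
97% treated), child open defecation downstream of latrine quality (93% →
80%), safe child-feces disposal (24% → 76%), and a 5-level ordinal potty-use
scale (cumulative odds ratio ≈ 37). The outcome model is logit with a
modest direct effect, yielding ≈ 14–15% control and ≈ 10% intervention
diarrhea prevalence and per-mediator true ACMEs of roughly −0.003 to −0.02
— the 0.5–2 percentage-point scale of the published mediation effects.

`true_acme_oracle()` is the parameter-recovery oracle: it simulates the
counterfactual system directly from the generating models — coupled
potential mediators $M(0), M(1)$ via common random numbers, expected
potential outcomes — and returns the true ACME/ADE/total with Monte-Carlo
SEs. Coupling makes severed-path configurations return exactly zero and
keeps linear configurations exactly proportional under shared seeds.

What a green test does **not** establish: the generator draws mediators
independently across rounds within a child (no behavioural persistence),
has no within-cluster random effects beyond what the block/cluster means
induce through treatment, no informative missingness, no spillover between
clusters, and no unmeasured mediator–outcome confounding — precisely the
assumption the real analysis cannot verify. Parameter recovery on this
world validates the estimators' arithmetic and calibration, not the causal
assumptions.

## Known limitations

* Sensitivity curves over unobserved-confounding correlation parameters are
  out of scope, as is joint decomposition of several mediators in one model
  (the emulated analysis works one mediator at a time).
* The dependent-mediator estimator is linear-probability by construction;
  for very rare outcomes its effect composition can leave $[-1,1]$ in
  extreme resamples.
* With many block fixed effects, the block-clustered parameter covariance
  is rank-deficient (rank ≤ number of blocks); the quasi-Bayesian sampler
  clips negative rounding-error eigenvalues at zero, which is exact for a
  genuinely PSD matrix.
* Step-2 association tables enter ordinal mediators as a numeric level
  trend (one row per mediator); step-3 outcome models use category
  indicators to avoid imposing linearity. The two standard errors answer
  slightly different questions, which mirrors the ambiguity in the emulated
  procedure.
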