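# crtmediate

Causal mediation analysis for cluster-randomized sanitation trials.

A multi-component rural sanitation intervention — latrine upgrades, child
feces management tools (potty, sani-scoop), behavioral promotion — reduced
caregiver-reported diarrhea among children under five in a blocked,
cluster-randomized trial. `crtmediate` is for epidemiologists and
biostatisticians who want to know *which component did the work*: it
decomposes the intervention's effect on diarrhea prevalence into the pathway
through each measured mediator (latrine quality indicators, latrine use
practices, feces management practices) and the residual direct pathway.

## The estimands

For treatment $T \in \{0,1\}$, mediator $M$ and binary outcome $Y$, with
$M(t)$ and $Y(t, m)$ the potential values,

- **ACME**$(t) = E[Y(t, M(1)) - Y(t, M(0))]$ — the part of the effect
  transmitted by the treatment moving the mediator;
- **ADE**$(t) = E[Y(1, M(t)) - Y(0, M(t))]$ — the direct remainder;
- **Total** $= E[Y(1, M(1)) - Y(0, M(0))] = \mathrm{ACME}(1) +
  \mathrm{ADE}(0) = \mathrm{ACME}(0) + \mathrm{ADE}(1)$,

all reported as prevalence differences, with averages weighted by the arm
proportions. A negative ACME is a protective pathway. Inference is
quasi-Bayesian Monte Carlo (parameter draws from the block-clustered sandwich
covariance) for causally independent mediators, and a varying-coefficient
linear structural-equation estimator with block bootstrap for latrine-use
mediators confounded post-treatment by latrine quality. Screening models are
log-binomial (modified Poisson on convergence failure), Poisson, or
proportional odds, all with CR1 cluster-robust variance. Analyses run
separately for monsoon and dry seasons, with the monsoon window derived from
daily rainfall (first to last day of ≥ 10 mm 5-day rolling average).

See `vignettes/mediation-methods.Rmd` for the full model account.

## Worked example

Simulate a trial with known mediation structure, then run the full
season-stratified three-step analysis:

```r
library(crtmediate)

cfg   <- synth_config(n_blocks = 30, seed = 7)   # 30 matched blocks, 8 rounds
trial <- generate_trial(cfg, oracle_mc_n = 1e5)
print(trial$truth)
#> <crt_synth_truth> oracle mc_n = 1e+05
#>                 mediator  season true_acme true_ade true_total oracle_se
#> 1       hygienic_latrine     dry   -0.0036  -0.0566    -0.0602   2.2e-05
#> 2       hygienic_latrine monsoon   -0.0035  -0.0556    -0.0591   2.1e-05
#> 3            child_od_u3     dry   -0.0053  -0.0548    -0.0601   4.4e-05
#> 4            child_od_u3 monsoon   -0.0052  -0.0538    -0.0590   4.3e-05
#> 5 feces_disposed_latrine     dry   -0.0189  -0.0413    -0.0602   5.8e-05
#> 6 feces_disposed_latrine monsoon   -0.0185  -0.0406    -0.0591   5.7e-05
#> 7              potty_use     dry   -0.0171  -0.0431    -0.0602   3.2e-05
#> 8              potty_use monsoon   -0.0168  -0.0423    -0.0591   3.1e-05

ana <- run_full_analysis(trial$records, default_catalog(),
                         c("age_months", "sex", "wealth"),
                         analysis_config(n_sims = 1000, n_boot = 500, seed = 7))
print(ana)
#> <crt_analysis> seasons: monsoon, dry
#>   monsoon: 4 mediators screened, 4 retained, 4 mediated
#>   dry: 4 mediators screened, 4 retained, 4 mediated
#>                mediator  season              method    n    acme     ade   total acme_p
#>  feces_disposed_latrine monsoon         quasi-bayes 1674 -0.0252 -0.0281 -0.0532  0.004
#>        hygienic_latrine monsoon         quasi-bayes 1674 -0.0116 -0.0403 -0.0519  0.092
#>               potty_use monsoon         quasi-bayes 1674  0.0068 -0.0595 -0.0526  0.690
#>             child_od_u3 monsoon         quasi-bayes 1674  0.0010 -0.0542 -0.0533  0.926
#>               potty_use     dry         quasi-bayes 1676 -0.0394 -0.0108 -0.0502  0.168
#>        hygienic_latrine     dry         quasi-bayes 1676 -0.0189 -0.0303 -0.0492  0.002
#>  feces_disposed_latrine     dry         quasi-bayes 1676 -0.0183 -0.0324 -0.0507  0.088
#>             child_od_u3     dry dependent-bootstrap 1676  0.0003 -0.0509 -0.0506  0.960
```

Reading the output: the generator's oracle says safe child-feces disposal
truly carries about −1.9 percentage points of the ~−6.0 point total effect.
The pipeline's estimate for that mediator is −2.5 points in the monsoon
season (p = 0.004) and −1.8 in the dry season — parameter recovery at a
single-trial sample size, with the remaining spread being sampling noise
(the test suite verifies calibration over 200 replicates). `child_od_u3` is
a latrine-use mediator: in the dry season, where the hygienic-latrine ACME
was significant, it is automatically routed to the dependent-mediator
estimator (`method = dependent-bootstrap`) with latrine quality as an
upstream post-treatment confounder. Each row's `acme + ade = total` up to
interaction asymmetry; `n` is held identical across that mediator's three
analysis steps.

The worked-example calculator reproduces published crude ratios from printed
arm prevalences:

```r
crude_ratio(10.0, 14.8)   # 0.68  (monsoon prevalence ratio)
crude_ratio(97.1, 76.1)   # 1.28  (hygienic latrine, step one)
```

Other entry points: `detect_monsoon()` / `assign_season()` (rainfall-based
season windows), `step1_screen()` / `screen_covariates()` / `step2_fit()`
(individual pipeline stages), `mediate_single()` / `mediate_dependent()`
(the estimators), `lagged_sensitivity()` (reverse-causation check with
previous-round mediators), `mediator_correlations()` / `polychoric_rho()`
(mediator overlap audit), `load_records()` / `write_records()` /
`render_table1()` / `render_mediation_figure_table()` (validated I/O and
report tables).

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch:
it simulates the default synthetic trial at the given seed, computes the
Monte-Carlo oracle truth, runs the full season-stratified mediation pipeline
at the published simulation settings (1000 quasi-Bayesian draws, 1000
bootstrap resamples), writes the screening and mediation tables next to the
output file, and writes the JSON report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
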