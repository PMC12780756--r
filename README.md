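# hteforest

Honest causal forests for heterogeneous treatment effects in large matched
register cohorts — with a calibrated synthetic cohort generator so the whole
pipeline can be validated end to end against known ground truth.

The package is aimed at epidemiologists and applied statisticians who study
how a childhood exposure (the motivating design is type 1 diabetes diagnosed
at ages 7–17 in a full-population register, with ~3000 exposed and ~79,000
matched controls) shapes adult outcomes — mortality, antidepressant use,
partnership, education, unemployment, income — and *for whom* the effects are
largest.

## What it computes

For each outcome $Y$, treatment $W$ and modifiers $X$, the target is the
conditional average treatment effect $\tau(x) = E[Y(1)-Y(0)\mid X=x]$,
estimated by an honest causal forest on locally centered data:

* out-of-bag regression forests for $m(x)=E[Y|X]$ and $e(x)=E[W|X]$, with
  residuals $\tilde Y = Y - \hat m$, $\tilde W = W - \hat e$;
* trees grown on gradient pseudo-outcomes
  $\rho_i = \tilde W_i(\tilde Y_i - \tilde W_i\tau_P)/A_P$, choosing splits
  that maximize $(\sum_L\rho)^2/n_L + (\sum_R\rho)^2/n_R$ with honesty
  (disjoint split/estimation halves per tree);
* CATE prediction by adaptive forest weights:
  $\hat\tau(x) = \sum_i\alpha_i(x)\tilde W_i\tilde Y_i \big/
  \sum_i\alpha_i(x)\tilde W_i^2$;
* doubly robust (AIPW) average effects and per-group effects with
  normal-approximation CIs;
* the heterogeneity workflow of pilot-forest covariate screening (keep
  covariates at or above mean split-frequency importance), 10-fold
  cross-fitted CATE quartile ranks, per-quartile AIPW effects, and
  standardized mean differences between the low- and high-effect groups.

The synthetic cohort module generates register-like data whose covariate
marginals, outcome margins, matched design (up to 26 controls per case on
region x sex x birth year), censoring (two outcomes unobservable for the
1990 birth cohort) and top-coded, rounded income mirror the published
descriptives of the motivating study, with configurable ground-truth effect
heterogeneity (a sex-modified antidepressant effect and a family-SES-modified
partnership effect).

## Worked example

```r
library(hteforest)

config <- dgp_config()                       # calibrated study design
cohort <- simulate_cohort(config, seed = 11) # 123,048 persons
kept   <- apply_exclusions(cohort)$cohort
matched <- match_controls(kept, max_per_case = 26, seed = 11)

outcome_summary(matched)[1:2, ]
#>              outcome    treated     control n_treated n_control
#> 1         died_by_30 0.02198163 0.009280384      3048     77583
#> 2 antidepressant_use 0.18431810 0.130812904      2691     69221
```

The treated group dies more than twice as often by age 30 (2.2% vs 0.93%)
and buys antidepressants more often (18.4% vs 13.1%), matching the margins
the generator is calibrated to. The heterogeneity pipeline then asks who is
most affected:

```r
an <- analyze_outcome(
  matched, "antidepressant_use", config,
  params = forest_params(num_trees = 250, min_node_size = 2000, mtry = 19),
  nuisance_params = forest_params(num_trees = 50, min_node_size = 200),
  seed = 7)

subset(an$effects, is.na(group) | group %in% c(1, 4))
#>   group    target   estimate          se      ci_low    ci_high     n
#> 1     1 group-ATE 0.02244650 0.013181356 -0.00338896 0.04828195 17978
#> 4     4 group-ATE 0.06990372 0.013748464  0.04295673 0.09685071 17978
#> 5    NA       ATT 0.05679902 0.007602733  0.04189767 0.07170038 71912

prof <- subset(an$profile, covariate == "female" & rank %in% c(1, 4))
prof[, c("rank", "mean")]
#>   rank mean
#> 1    1    0
#> 2    4    1
```

Interpretation: the cross-fitted CATE quartiles separate by sex — in this run
perfectly, with the low-effect quartile all male and the high-effect quartile
all female (so the female SMD between the extreme groups is reported as
missing: both groups have zero spread). The rank-4 AIPW effect on
antidepressant use, +7.0 points [4.3, 9.7], sits well above the rank-1 effect
of +2.2 points [-0.3, 4.8], recovering the heterogeneity the generator
injected (`true_cate(cohort, config, "antidepressant_use")` is
`0.01 + 0.07 * female`, i.e. +1 point for men and +8 for women).

A thin command-line wrapper (`inst/cli/hteforest-cli.R`) exposes
`simulate`, `match`, `analyze` and `run-all` over CSV/YAML files.

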