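---
title: "Honest causal forests for matched register cohorts: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Honest causal forests for matched register cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The estimation problem

`hteforest` estimates conditional average treatment effects (CATEs) of a
childhood exposure — here, type 1 diabetes diagnosed at school age — on adult
health and social outcomes in a matched register-style cohort, and asks
whether those effects vary across the population. The estimand for outcome
$Y$ with treatment $W$ and modifiers $X$ is

$$\tau(x) = E[Y(1) - Y(0) \mid X = x],$$

identified under unconfoundedness given the 38 pre-treatment covariates. All
effects are additive on the outcome's own scale: probability points for the
binary outcomes (mortality by 30, antidepressant purchase, living without a
partner, basic education only), months/year for annualized unemployment, and
euros/year for income.

The estimation machinery is a generalized-random-forest-style honest causal
forest with local centering:

1. **Local centering.** Honest regression forests estimate the marginal
   outcome surface $m(x) = E[Y \mid X=x]$ and the propensity
   $e(x) = E[W \mid X=x]$; out-of-bag residuals
   $\tilde Y_i = Y_i - \hat m^{(-i)}(X_i)$,
   $\tilde W_i = W_i - \hat e^{(-i)}(X_i)$ orthogonalize the problem, so the
   causal forest regresses residuals on residuals. The propensity is clipped
   to $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 0.01$, below the
   design propensity of the matched cohort ($\approx 3.7\%$ treated), so the
   clip guards degenerate leaves without distorting the bulk.
2. **Gradient splitting.** In a node $P$ the residual-on-residual solution is
   $\tau_P = \sum \tilde W_i \tilde Y_i / \sum \tilde W_i^2$; with
   $A_P = \mathrm{mean}(\tilde W_i^2)$, pseudo-outcomes
   $\rho_i = \tilde W_i(\tilde Y_i - \tilde W_i \tau_P)/A_P$ (which sum to
   zero) turn heterogeneity search into a mean-shift problem: the chosen
   split maximizes $\Delta = (\sum_L \rho)^2/n_L + (\sum_R \rho)^2/n_R$ over
   candidate covariates and all midpoints between consecutive sorted values,
   i.e. it maximizes differences in children's CATEs weighted by child sizes.
3. **Honesty.** Each tree draws a subsample without replacement and splits it
   into a structure half (J1) and an estimation half (J2). Splits use J1
   outcomes only; leaf membership is recorded from J2. The minimum node size
   is enforced on *both* halves so that every estimation leaf is estimable.
   (A consequence is that J2 covariate *counts* participate in split
   feasibility; J2 *outcomes* never do, which is the property honesty needs
   and the property the test suite asserts.)
4. **Prediction.** Adaptive weights $\alpha_i(x)$ count estimation-leaf
   co-membership across trees; the CATE is the forest-weighted
   residual-on-residual slope
   $\hat\tau(x) = \sum_i \alpha_i(x)\tilde W_i\tilde Y_i /
   \sum_i \alpha_i(x)\tilde W_i^2$. Training-row predictions are out-of-bag.
   If the weighted residual treatment variance at a query is zero, the
   forest-wide slope is returned and the event is counted and warned about.
5. **Average effects.** Per-person AIPW scores
   $\Gamma_i = \hat\tau_i + \frac{W_i-\hat e_i}{\hat e_i(1-\hat e_i)}
   (Y_i - \hat m_i - (W_i - \hat e_i)\hat\tau_i)$ give doubly robust
   averages: the ATE is $\bar\Gamma$; the effect on the treated weights the
   scores by $\hat e_i$ (the standard doubly robust ATT weighting — the
   variant is not pinned down by the study description, so it is validated by
   simulation: consistency under a constant-effect randomized design and
   robustness to a deliberately corrupted outcome model). Confidence
   intervals are normal-approximation $\pm 1.96\,\mathrm{se}$; CATE-level
   variance estimation (bootstrap of little bags) is out of scope, since
   inference is reported only for group-level effects.
6. **Heterogeneity workflow.** A pilot forest on all covariates is screened
   by depth-decayed split-frequency importance
   ($\sum_{d \le 4} d^{-2}\,\mathrm{freq}_d(v)$, normalized); covariates at
   or above the mean importance enter the final forest. Cross-fitted ranks
   divide the sample into 10 random folds, train the whole pipeline
   (centering, pilot, selection, final forest) on 9 folds and predict the
   held-out fold, so nobody influences the forest that ranks them. The pooled
   predictions are cut into quartiles (rank 1 = low effect, rank 4 = high
   effect); covariate means per rank and standardized mean differences
   (SMD $= (\bar x_4 - \bar x_1)/\sqrt{(s_1^2+s_4^2)/2}$) profile the most
   and least affected groups.

# The synthetic register cohort

The registers behind the emulated study are confidential, so the package
ships a generator whose defaults *are* the study conditions: a source pool of
3048 treated persons plus 120,000 controls born 1981-1990 in 17 regions;
exclusion flags (diagnosis before 7, missing covariates, death or emigration
before 18) at small configurable rates; stratified matching of up to 26
controls per case on (region, sex, birth year), which lands near the
published matched size of ~79,000 controls.

**Covariates.** The 38 modifiers follow a single-latent-factor model: a
standard normal family socioeconomic factor $Z$ loads on parental education
and employment, household economic indicators, and postcode composition;
marginals are calibrated exactly — binary and bounded-share intercepts are
solved by Gaussian quadrature, count/lognormal/ordinal moments analytically —
so sample means match the published full-population cells (49% women, 76%
homeowners, household size 4.55, earnings 26,300, and so on). One factor is
the minimal correlation structure that supports an interpretable family-SES
modifier; the observable composite `ses_index` (parental education, household
earnings, homeownership, social assistance with a negative sign) is
standardized with a quadrature-computed normalization, so effects defined on
it are exact functions of the covariates and `true_cate()` has a closed form.
Father covariates are mean-imputed when the `missing_parent` flag is set,
mirroring the reference-group imputation of the emulated study.

**Treatment.** Exactly 3048 treated are drawn by weighted sampling without
replacement with weights $\exp(\beta^\top x_{std})$ (a fixed case count, as
in the emulated design, rather than Bernoulli draws). The default tilt
reproduces the published treated-group imbalances: more pre-diagnosis
hospital visits, household diabetes and siblings, and a treated share of
women near 0.43 against 0.49 in the population.

**Outcomes.** Mortality is drawn first (logistic baseline in the SES index
plus a +1.4 percentage-point additive treated effect, calibrated to 0.9%
control / 2.3% treated); all other outcomes are drawn for survivors only.
Binary outcomes are logistic baselines with additive probability-scale
effects; intercepts are re-solved on each generated cohort's control
survivors, so the configured control-group means (13.1% antidepressants,
31.8% unpartnered, 10.3% basic education) are met exactly up to draw noise.
Unemployment is zero-inflated scaled Beta on [0, 12] months/year
(P(any) = 0.25, conditional mean 4.08) with the treatment effect on the
zero part sized to +0.16 months/year; income is lognormal, scaled so the
control-survivor mean is 27,453, shifted by -1756 for the treated,
rounded to hundreds and top-coded at 150,000 (the published cap is not
public; this default is configurable). Antidepressant and income outcomes are
censored for the 1990 birth cohort. Baselines deliberately carry **no direct
sex term**: matching is on sex, so a sex-dependent baseline would shift the
matched-control margins away from their calibration targets; the sexes
differ in outcome only through the *effect* modifier below. Likewise the
treatment-model covariates carry no SES loading, so the matched control group
inherits the calibrated margins exactly in expectation.

**Ground-truth heterogeneity.** Two modifiers are on by default, both sized
from the published group contrasts rather than tuned: the antidepressant
effect is $\tau(x) = 0.010 + 0.070\,\mathrm{female}$ (treated mean
$13.1 + 1.0 + 7.0 \times 0.43 \approx 17.1\%$; quartile effects spanning
roughly 1 to 8.5 points), and the partnership effect is
$\tau(x) = 0.040 - 0.025\,\mathrm{ses}$ (span roughly 2.8 to 7.1 points).
Because effects are additive on the probability scale, `true_cate()` is exact
and the generator warns if any probability ever needs clipping (isolated
events in the extreme SES tail are tolerated and counted).

**What the generator does not emulate.** Register linkage errors, real
regional covariate gradients, cohort trends in outcome baselines, true T1D
etiology, or post-18 emigration. Passing tests therefore demonstrate that the
estimation machinery recovers known truths under a realistic *design*
(sample sizes, margins, censoring, matched propensity ~3.7%), not that the
substantive findings of any real cohort are reproduced.

# Defaults, tuning and numerical choices

* Forest defaults: 500 trees, subsample fraction 0.5, honesty fraction 0.5,
  minimum node size 5, mtry $\lceil\sqrt p\,\rceil$. Automatic
  cross-validated tuning is intentionally replaced by these fixed,
  overridable defaults.
* For the register-scale heterogeneity analysis (n about 80,000, 3.7%
  treated) the package's own analyses use a larger minimum node size of about
  2.5-3% of the sample (2000) and mtry of p/2 (19), with 250 trees per
  forest and 50-tree/min-node-200 nuisance forests. Two reasons: (i) the
  tiny treatment variance ($\tilde W$ variance about 0.036) makes leaf-level
  slopes noisy, so wide leaves are the binding statistical constraint; and
  (ii) a large minimum node size confines candidate thresholds to the
  central part of each continuous covariate, which curbs the
  multiple-threshold selection advantage continuous covariates otherwise
  enjoy over binary modifiers in split-frequency importance. The acceptance
  suite verifies that with these settings the pilot stage retains the sex
  modifier and the extreme rank groups separate sharply by sex. These
  problem sizes and settings are the package's documented analysis choices.
* Splitting ties are broken deterministically (lowest covariate index, then
  lowest threshold); thresholds are midpoints between consecutive distinct
  splitting-half values; a guard promotes a midpoint that underflows onto the
  left value to the right value.
* All forest randomness is keyed on (seed, tree index, node counter) and
  person *ids*, and node accumulations run in (value, id)-sorted order, so
  results are bit-reproducible under row permutation. The matching stage
  keys an RNG stream per (seed, stratum), so matched samples are invariant
  to stratum and row reordering. Exact reproduction of the original study's
  PRNG stream is out of reach and not attempted.
* Quartile ranks are cut on the pooled cross-fitted predictions (not
  per-fold) so ranks are globally comparable; exact ties break by person id,
  keeping group sizes within 3 of each other. Constant predictions collapse
  to a single rank with a warning. Per-fold quartiles are the obvious
  alternative; pooled cuts were chosen for comparability and near-equal
  sizes.
* Group comparisons use the chi-square test without continuity correction
  for dichotomous outcomes and the Welch t-test for continuous ones.
* Per-outcome analysis samples: mortality uses all matched rows; every other
  outcome drops deceased and censored rows first, mirroring the
  "alive and resident" conditioning of the emulated design, with the usual
  selection caveat that conditioning on survival can attenuate effects.

# Validation strategy

The test suite validates each layer against an independent oracle: node
pseudo-outcomes against hand arithmetic; the split search against exhaustive
brute-force enumeration; forest weights against an R re-implementation walking
the exported tree structures; `true_cate()` against brute-force
potential-outcome Monte Carlo; AIPW against algebraic identities, a
constant-effect randomized design, and a corrupted-outcome-model double
robustness check; the rank pipeline against null calibration (coverage of
group CIs, no spurious rank-4 excess) and against injected monotone and
sex-modified heterogeneity; and the generator against the published margins
within three Monte-Carlo standard errors across seeds. Problem sizes in the
suite are scaled-down versions of the same designs (for example ten seeds at
n = 2000 instead of hundreds, and a single register-scale seed for the
recovery check).

# Known limitations

* CATE-level confidence intervals are not provided; only group-level AIPW
  inference is.
* Split-frequency importance retains a residual bias toward continuous
  covariates; the large-min-node analysis setting mitigates but does not
  remove it. Permutation importance would be the principled alternative and
  is out of scope.
* Mortality is a binary 30-year endpoint, not a survival model; no
  principal-stratification correction is applied for death-censoring of the
  other outcomes.
* The matched design is emulated with stratum-level pooled control draws
  (min(26c, available) per stratum), which is distributionally equivalent to
  per-case draws when controls are exchangeable within strata.
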