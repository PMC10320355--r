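---
title: "Model-averaged meta-analysis robust to publication bias: models, numerics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-averaged meta-analysis robust to publication bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Publication bias — the preferential publication of statistically significant
results — inflates naive meta-analytic effect size estimates and the apparent
evidence for an effect. Single adjustment methods (selection models, PET,
PEESE, trim-and-fill, ...) each perform well only under particular research
conditions (true effect size, heterogeneity, selection strength), and those
conditions cannot be estimated without having already adjusted for the bias.
Model averaging resolves this circularity: fit an ensemble spanning the
plausible data-generating processes and let the marginal likelihoods decide
how much each model contributes to the pooled inference.

`robmeta` implements such an ensemble for correlation data on the Fisher z
scale, together with a corpus-level pipeline that quantifies, across many
meta-analyses, how much evidence and effect size shrink once publication bias
is accounted for, and a synthetic-corpus generator that provides
ground-truthed test beds for every stage.

## The model ensemble

Every member combines three binary research hypotheses, each with prior
probability 1/2:

* **Effect**: point mass at `mu = 0`, or a continuous prior on the mean
  effect. The default continuous prior is `Normal(0, 1)` on the Cohen's d
  scale (a plausible range for psychology); an alternative is the Oosterwijk
  prior `Student-t+(location 0.35, scale 0.10, df 3)`, elicited for typical
  (positive, small-to-medium) effects in the field and available via
  `effect_prior = "oosterwijk"`.
* **Heterogeneity**: `tau = 0`, or `tau ~ Inverse-Gamma(shape 1, scale
  0.15)` on the d scale, matching empirical heterogeneity estimates in
  psychology.
* **Publication bias**: absent, or one of nine components — six step
  weight-function selection models and the PET and PEESE meta-regressions.

The six weight functions combine one- and two-sided p-value cut-offs at
significance and marginal significance: two-sided {.05} and {.05, .10};
one-sided {.05}, {.025, .05}, {.05, .5} and {.025, .05, .5}. Weights follow
the cumulative unit Dirichlet prior: interval masses `eta ~ Dirichlet(1,
..., 1)` are cumulated from the least significant interval up, so the most
significant interval has weight 1 and weights never increase with the
p-value. PET and PEESE regress the effect on the standard error and squared
standard error with `Cauchy+(0, 1)` and `Cauchy+(0, 5)` priors (d scale) on
the coefficients, enforcing the positive small-study relationship.

Within each effect-by-heterogeneity cell the bias-present mass is split
equally between the selection family and the PET/PEESE family, then equally
within family: 1/8 for the no-bias member, 1/96 per selection model, 1/32
for PET and for PEESE — 36 models totalling probability 1.

### Effect scales

Primary studies enter as correlations `r` with sample sizes `n` (or
directly as Fisher z with a standard error). All likelihoods operate on
`z = atanh(r)` with `se_z = 1/sqrt(n - 3)`: the z statistic is unbounded,
nearly normal, and orthogonal to its standard error — the last property is
an assumption of PET/PEESE. Priors stated on the d scale are rescaled by the
exact change of variables `d = 2 sinh(z)` (the composite of `d = 2r /
sqrt(1 - r^2)` and `r = tanh(z)`), with a `prior_rescale = "linear"` switch
for the small-effect linearization `d = 2z`; for effects below `|z| = 0.2`
the two differ by under 1%. A scale parameter has no exact pushforward
under a nonlinear mean map, so the heterogeneity prior rescales by the
linearization `tau_z = tau_d / 2` in both modes, and the PEESE coefficient
doubles (`z = mu_z + 2 c_d se_z^2` under `d = 2z`) while PET's is scale
free. Results are reported back on the r scale as the posterior mean of
`tanh(mu)` under the model-averaged mixture — the mean of the
back-transform, not the back-transform of the mean; both are exposed.

## Inference

Each model's marginal likelihood integrates its likelihood against its
priors over 0–5 free dimensions. Posterior model probabilities are
proportional to prior probability times marginal likelihood (log-sum-exp
throughout); component posterior probabilities (effect, heterogeneity,
bias) are sums over the relevant members, and the inclusion Bayes factor is
the posterior-to-prior odds ratio. The model-averaged posterior of `mu` is
the probability-weighted mixture of conditional posteriors, point-effect
members contributing a point mass at zero; central 95% intervals come from
the mixture's distribution function with the point mass included.

### Numerical methods

The integration scheme (see `integration_settings()`) is chosen per model:

* **0 dimensions** (point effect, point heterogeneity, no bias): closed
  form.
* **Up to 3 dimensions**: deterministic Gauss–Legendre quadrature on
  prior-quantile-transformed coordinates, so the prior is absorbed into the
  measure. Two structural obstacles required care. First, a precise
  meta-analysis concentrates the likelihood in `mu` on a sliver of the
  prior, and in PET/PEESE models the conditional centre of `mu` moves with
  the coefficient (a diagonal ridge); a fixed tensor grid cannot track
  either. The "linear" parameter — `mu`, or the regression coefficient when
  `mu` is a point mass — therefore gets its own quadrature window around
  its conditional weighted-least-squares centre at every outer node,
  shifted by the local gradient of the selection term where applicable and
  intersected with the prior's bulk. Second, the cumulative Dirichlet
  weights are the descending order statistics of iid uniforms; the sorting
  map has a kink that defeats Gauss–Legendre, so the smooth
  sequential-maximum transform is used instead, with a power substitution
  `v = t^4` concentrating nodes near zero weights, where the weighted
  likelihood can spike under strongly significant data. Outer dimensions
  are windowed by a coarse scan that discards regions at least `e^25` below
  the likelihood peak. The error estimate is the difference against a
  half-resolution pass; one refinement doubles the nodes if it exceeds
  `rel_tol` (default 0.01).
* **4–5 dimensions** (selection models with several weight steps plus free
  `mu`/`tau`): defensive importance sampling — half the draws from the
  priors, half from a normal proposal around the pooled estimate for `mu`
  and from the same `t^4` tilt for the weights — with the standard error of
  the log marginal likelihood reported.

Results whose error estimate exceeds five times `rel_tol` (quadrature) or
0.1 (Monte Carlo) are flagged, and `fit_ensemble()` carries the flags into
its result rather than failing. The `"small"` preset (4,000 draws, reduced
node counts) is used throughout the test suite and the acceptance script;
it fits a 30-study, 36-model ensemble in roughly two seconds, with Monte
Carlo standard errors around 0.05–0.09 on the log scale for the handful of
high-dimensional members. The default preset (20,000 draws) halves those
standard errors. Hot likelihood loops are implemented in C++ (Rcpp); the
scalar R implementations of the same likelihoods remain the documented
operations and the two routes are cross-checked in the tests, as is the
selection likelihood against `metafor::selmodel()`, which agrees to machine
precision at the frequentist MLE.

## The synthetic corpus generator

`simulate_corpus()` emulates the structure of a large meta-science corpus:
articles containing several meta-analyses, each a set of primary studies
generated from the random-effects model `theta_i ~ Normal(mu, tau)`,
`z_i ~ Normal(theta_i, 1/sqrt(n_i - 3))`, and filtered by
significance-based publication selection that mirrors the weight-function
form (per-interval publication probabilities). The published study count
`K` is fixed by design — meta-analyses are observed at their published
size. Defaults, chosen once as a realistic corpus for the field:

* 90 articles with 4–5 meta-analyses each (about 400 meta-analyses, the
  scale of the corpus the pipeline is designed for); a `"small"` preset (10
  articles, 20 meta-analyses, `K <= 20`) keeps continuous-integration runs
  fast.
* True effects `mu_z ~ Normal(0.15, 0.15)`: mostly small positive effects
  with a null-heavy left tail.
* Heterogeneity `tau_z ~ Inverse-Gamma(1, 0.075)`, the empirical
  heterogeneity prior on the z scale.
* Sample sizes log-normal with median 60 (log-sd 0.5, minimum 8), typical
  primary-study sizes in experimental psychology.

The generator does **not** emulate p-hacking (the ensemble contains no
p-hacking model, so adding it would change what a passing test means),
correlated estimates within a meta-analysis, non-normal primary outcomes,
or effect sizes harmonized from other metrics. Tests passing on this
generator therefore certify the estimation machinery under the ensemble's
own assumptions, not robustness to those violations.

## The corpus pipeline

For each meta-analysis, `analyze_one()`:

1. orients the studies so the random-effects estimate is positive (the
   PET/PEESE priors and one-sided weight functions assume selection favours
   the positive direction); the flag is kept and estimates are reported
   with the original sign restored, while adjustment columns stay on the
   oriented scale so a negative adjustment always means correction toward
   zero;
2. fits the random-effects comparator by REML via `metafor::rma()` (the
   modern default; a `rema_method` switch selects other estimators), with
   an equal-effects fallback for single-study inputs;
3. fits the bias-unadjusted model average (BMA: the four bias-absent
   members, prior effect probability renormalized to 1/2) and the full
   36-model ensemble, and records estimates, posterior probabilities,
   Bayes factor evidence categories (strong/moderate null or alternative at
   1/10, 1/3, 3, 10), probability changes and r-scale adjustments.

`summarize_corpus()` reports medians and interquartile ranges of the
posterior probability of the effect before and after adjustment, category
percentages, the proportion of meta-analyses whose probability moved at
most 0.05, medians/IQRs of the three estimates and the two adjustments,
and the proportion adjusted by less than r = 0.03 against BMA — the two
thresholds are configurable and default to those corpus studies report.
Meta-analyses whose ensemble fit fails are carried as flagged rows with the
failure reason and excluded from summaries, never silently dropped.

Two corpus-level models interrogate the adjustments:

* `heterogeneity_regression()` predicts the z-scale adjustment
  attributable to publication bias from the REML heterogeneity estimate,
  with the unadjusted effect size as a centred covariate (larger effects
  show larger absolute bias and larger tau). Coefficients carry a
  unit-information conjugate prior (`beta | sigma^2 ~ Normal(0, n sigma^2
  (X'X)^-1)` with Jeffreys' prior on the shared `sigma^2`), which makes
  every submodel's marginal likelihood — and hence each coefficient's
  inclusion Bayes factor by leave-one-out model comparison — available in
  closed form. An exact conjugate form was preferred over reusing the
  numerical quadrature engine: it is deterministic, instantaneous and has
  no integration error to propagate into Bayes factors. Heterogeneity is
  left on its raw scale so the intercept is the expected adjustment of a
  homogeneous meta-analysis; standardized slopes are reported alongside.
* `three_level_adjustment_model()` fits the hierarchical model
  `adjustment ~ method fixed effect + article intercept + meta-analysis
  intercept + residual` — estimates from one meta-analysis are correlated,
  as are meta-analyses within an article. Priors are weakly informative:
  `Normal(0, 1)` on fixed effects (adjustments are small on the r scale)
  and `half-t(3, 0, 0.5)` on the three standard deviations. Sampling is
  Gibbs via JAGS with fixed per-chain seeds, using multiplicative parameter
  expansion for the intercept scales (whose expanded form has exactly the
  half-t prior) and post-sweeping of intercept means into the fixed
  effects; without these, near-zero variance components and the
  unidentified overall-level direction mix arbitrarily slowly. Convergence
  requires split R-hat below 1.01 on the reported fixed effects and below
  1.05 on the nuisance scales; otherwise the function errors with the
  diagnostics.

`report()` renders the record table, a key-value summary CSV, a markdown
summary, and three figures (probability before/after with marginal
densities; estimate scatters against both comparators; estimate and
adjustment densities). The text artifacts use fixed numeric formatting and
are byte-reproducible under identical seeds and configuration; the PDF
figures embed a creation timestamp that the graphics device does not expose
control over, so byte-level determinism is asserted for the CSV/markdown
outputs.

## Design decisions on genuinely open points

* **Exact versus linear d-to-z prior rescaling**: both provided; the exact
  transform is the default for correctness at large effects, and the two
  are indistinguishable in the small-effect regime where the priors
  concentrate.
* **Boundary p-values** are assigned to the more significant interval.
* **p-values are recomputed from `(z, se_z)`** rather than taken from the
  primary studies' own test statistics; on the Fisher z scale these are
  the p-values the selection models' normalizing constants integrate over.
* **Orientation before fitting** is this package's choice (flag emitted),
  not asserted as the behavior of any other analysis.
* **r-scale point estimate**: posterior mean of `tanh(mu)`; `tanh` of the
  z-scale mean is also returned for comparison.
* **Single-study meta-analyses** are fitted (real corpora contain them)
  with a warning below three studies; results then lean heavily on the
  priors, as the uninformative-data tests document.

## Known limitations

* With modest per-study information and no true selection, the bias-present
  half of the ensemble retains posterior weight and its conditional
  estimates sit below the unadjusted ones, so the model-averaged estimate
  shrinks somewhat toward zero; the effect fades as per-study sample sizes
  or study counts grow. The one-sided nature of PET/PEESE (the coefficient
  prior allows only positive small-study relationships) makes this
  shrinkage asymmetric: chance positive se–effect correlation is absorbed
  by the bias models, chance negative correlation is not. The acceptance
  script quantifies this on a fixed no-selection corpus.
* When all studies share one standard error, the PET/PEESE mean structure
  `mu + c se^k` is exactly collinear with the intercept, and point-effect
  PET/PEESE members fit a nonzero mean perfectly; evidence for an effect
  then saturates below certainty no matter how strong the signal.
* A single observed p-value is never uninformative about selection: even a
  study with an enormous standard error moves the bias component's
  posterior away from 1/2 (the effect and heterogeneity components do
  return to equipoise).
* The Monte Carlo members' log marginal likelihoods carry standard errors
  around 0.05–0.09 under the `"small"` preset; posterior model
  probabilities of individual high-dimensional selection members inherit
  that noise, though component-level probabilities are far more stable.
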