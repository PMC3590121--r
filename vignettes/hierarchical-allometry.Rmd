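---
title: "Hierarchical Bayesian estimation of tree and branch allometric scaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian estimation of tree and branch allometric scaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allomhb)
```

## The model

Allometric theory describes how a plant trait $Y$ scales with size through a
power law $Y = a X^b$. For trees and branches the natural size variable is
branch (or basal) diameter $D$, and competing theories make sharp,
closed-form predictions for the exponent $b$: Metabolic Scaling Theory
(MST) predicts $b = 2/3$ for length, $8/3$ for total and stem mass and $2$
for leaf mass; Geometric Similarity (GEOM) predicts $1$, $3$, $3$, $2$; and
Stress Similarity (STRESS) predicts $1/2$ for length and $5/2$ for
aboveground mass, with no prediction for the mass partitions. Deciding
which theory a harvested dataset supports therefore reduces to estimating
exponents — with honest uncertainty — at every level where the theories
operate: individual trees, species, and the community at large.

`allomhb` fits the four trait relationships simultaneously on the log
scale. With $y_i$ the vector of the four log traits (log length, log
aboveground dry mass, log stem dry mass, log leaf dry mass) of observation
$i$, nested in tree $t(i)$ and species $s(t)$:

$$y_i \sim \mathrm{MVN}\!\left(\alpha_{t(i)} + b_{t(i)} \log\rho_i,\;
\Sigma\right)$$

where $\alpha_{t}$ and $b_{t}$ are per-tree 4-vectors of intercepts
($\alpha = \log a$) and exponents, $\Sigma$ is a full $4 \times 4$ residual
covariance (the traits of a branch are correlated even after conditioning
on diameter — aboveground mass is literally stem plus leaf mass), and
$\rho_i$ is the *latent true diameter*. The observed diameter is treated as
a noisy measurement in the Berkson errors-in-variables sense:

$$D_i \sim \mathrm{LogNormal}(\log\rho_i,\ \sigma_\rho^2),$$

with $\sigma_\rho = 0.05$ by default (about 5% relative error on a field
calliper/tape measurement; configurable in `allom_model_config()`). Each
$\log\rho_i$ carries a uniform prior over a wide support
($[\log 0.5, \log 500]$ cm by default).

Partial pooling ties the levels together, independently per trait and per
parameter:

$$\alpha_{t} \sim N(\alpha_{s(t)},\ \sigma_{a}^2), \quad
  b_{t} \sim N(b_{s(t)},\ \sigma_{b}^2), \qquad
  \alpha_{s} \sim N(A,\ \tau_A^2), \quad
  b_{s} \sim N(B,\ \tau_B^2).$$

$A$ and $B$ are the global (interspecific) normalization constants and
exponents. The tree-level standard deviations are shared across species
(one $\sigma$ per trait and parameter), matching the usual
variance-component summary with a single tree-level variance per trait.
Hyperpriors are non-informative: uniform on $A \in [-20, 20]$,
$B \in [-5, 5]$ and every hierarchical sd on $[0, 10]$, and a Wishart with
5 degrees of freedom and identity scale on the residual precision
$\Sigma^{-1}$. All bounds are configurable and serialized into the run
manifest by `run_pipeline()`.

Two modelling choices deserve a note, because the problem statement leaves
them open. First, the hierarchy is placed on $\alpha = \log a$, not on $a$:
the fitting scale is the log scale, normality there keeps every
conditional conjugate, and a normal prior on $a$ itself would mix a
left-bounded quantity with an unbounded hierarchy. Second, the measurement
error is applied to *all* observations at the same $\sigma_\rho$; a variant
in which only a subset of trees is error-prone would need per-tree error
indicators the data cannot identify.

## Sampling

`run_mcmc()` is a Metropolis-within-Gibbs sampler with conjugate blocks
wherever the model admits them:

1. each tree's stacked $(\alpha_t, b_t)$ vector (8 components) is drawn
   jointly from its multivariate normal full conditional, given $\Sigma$,
   the latents and its species-level means;
2. species and global means are scalar normal conjugate updates (global
   means truncated to their uniform supports);
3. $\Sigma^{-1}$ is a conjugate Wishart draw
   (`conjugate_update_precision()`);
4. the sixteen hierarchical sds and every latent $\log\rho_i$ get
   random-walk Metropolis updates on the log (respectively identity) scale.

Random-walk scales adapt by Robbins–Monro toward a 35% (scalars) / 44%
(latents) acceptance rate *during burn-in only* and are frozen at its end,
so the post-burn-in chain is a fixed Markov kernel and ergodicity is not
compromised. Initial values come from per-tree ordinary least squares on
the log data (species-pooled OLS for trees too small to regress), the
pooled OLS residual covariance, and latents at the observed log diameters.

The historical protocol for this class of analysis — 3 chains of
1,000,000 iterations, thinned by 10 after a 200,000-iteration burn-in — is
available as `study_sampler_control()`. The package default is a
desk-scale protocol, 3 chains of 6,000 with burn-in 2,000 and thinning 2,
which mixes well on datasets of the bundled fixture's size (about 300
observations, 25 trees): potential scale reduction factors on the global
parameters are routinely below 1.01, and the Heidelberger–Welch
stationarity test (computed with `coda`, the implementation the original
protocol used) passes. Both diagnostics are exposed (`rhat()`,
`heidelberger_welch()`) and `run_pipeline()` applies an R-hat ≤ 1.1 gate on
the global parameters.

## The synthetic-data generator

`generate_dataset()` simulates data with *exactly* the statistical
structure the model assumes, so that estimation can be validated against
known truth without any field download: species and tree parameters drawn
from the hierarchy, latent log diameters uniform over the log of the
configured diameter range (the even-leverage choice in log–log space,
absent any empirical diameter distribution to imitate), lognormal observed
diameters, and the four log traits jointly multivariate normal. Masses are
generated as *subtree aggregates* — all biomass distal to the branching
node — which is the quantity the model regresses on diameter.

Two emission modes differ only in how masses appear in the records table.
In `model-exact` mode the aggregated masses are written directly (as wet
weights, dividing by the species dry:wet ratio) with no parent links. In
`raw-field` mode each tree also receives a branching topology and the
aggregates are disaggregated into per-segment wet masses: a segment's mass
is its own aggregate minus its daughters' aggregates. Because aggregates
are independent draws around the power law, a node's daughters can
overflow its aggregate; nodes are therefore attached greedily, in
decreasing diameter order, to a random earlier node with sufficient mass
slack, and a node for which no feasible parent exists has its trait vector
redrawn (counted and reported). A chain attachment is always feasible once
masses are monotone, so the procedure terminates. Preprocessing a
raw-field table (`allom_observations()`: downstream aggregation, dry-mass
conversion, the inclusive ≥ 2 cm diameter filter, log transform) must — and
in tests does — reproduce the generated aggregates to arithmetic
tolerance.

One structural subtlety: the model treats all four log traits as a joint
multivariate normal, but the field-record schema stores only wood and leaf
wet masses, so any table rebuilt from records has aboveground mass
recomputed as stem + leaf. The two are consistent in distribution but not
draw-for-draw. Parameter-recovery tests therefore use the generator's
in-memory observation table (`$observations`), which carries the exact
generated traits; the records path is exercised by the preprocessing
round-trip and the pipeline.

`study_fixture()` reproduces the harvest design of the motivating field
study: three species with 10, 5 and 10 trees carrying 103, 30 and 128
branches plus one main stem per tree — 286 observations, all with observed
diameter at least 2 cm (the measurement error is truncated from below,
emulating a field protocol that only records branches above the calliper
threshold). Default true exponents are $(0.75, 2.65, 2.70, 2.0)$ for
length, aboveground, stem and leaf mass — inside the ranges reported for
savanna trees — with intercepts chosen so that stem + leaf ≈ aboveground
mass across the diameter range, and residual sds (0.25, 0.20, 0.20, 0.60
on the log scale) that put trait $r^2$ in the 0.85–0.95 range typical of
such data. Hierarchical spreads default to modest heterogeneity
($\tau_B = 0.05$, $\sigma_b = 0.03$ per trait, twice that for
intercepts): species-level variance estimates from three species are too
weakly identified (their credible intervals span orders of magnitude) to
serve as generative truth, and tree-level variances in this literature are
consistently tiny. Units are cm (diameter), m (length) and kg dry mass;
only the intercepts depend on this convention.

What the generator does *not* emulate: real diameter distributions
(log-uniform is a structural stand-in), fire/browsing/competition effects
on architecture, bark, below-ground biomass, or within-tree dependence
beyond the tree level. Passing recovery tests therefore demonstrate
correctness of the estimation machinery under the model's own assumptions,
not robustness to field misspecification.

## Posterior predictive checks

`allom_ppc()` simulates one replicate dataset per retained posterior draw
(draws subsampled evenly to the requested count) and computes, per trait,
two discrepancy statistics: the trait mean, and the sum of squared
deviations from the draw's mean surface. The Bayesian p-value $P_B$ is the
fraction of draws whose replicate statistic is at least as large as the
observed one — ties count as extreme, a convention that only matters for
degenerate data. Values near 0 or 1 flag lack of fit; on data simulated
from the model itself both statistics fall well inside $[0.1, 0.9]$
(checked in the test suite). Goodness of fit is summarized by $r^2$, the
squared Pearson correlation between each observed log trait and its
posterior-mean prediction; a zero-variance trait yields `NA` with a
warning rather than an arbitrary number.

## Scoring the theories

`compare_scaling_models()` assembles the 95% equal-tailed credible interval
of the exponent for every unit at every level — with the bundled fixture
that is 25 trees + 3 species + 1 global = 29 intervals per scaling
relationship — and flags, for each theory, whether its predicted exponent
lies inside each interval. Predictions are compared as exact rationals at
full double precision (no rounding of $2/3$ to 0.67). A model's support is
the percentage of defined comparisons included; STRESS's undefined stem-
and leaf-mass cells are excluded from its denominator, a convention the
output records by reporting the defined-comparison count alongside the
percentage. The best model is the argmax of the overall percentage, with
ties reported as a set rather than broken. Species differences are
summarized by `contrast_probability()`: the fraction of pooled posterior
draws in which one species' exponent exceeds another's.

## Numerical choices and limitations

* Quantiles use R's default interpolated order statistics (type 7); with
  continuous draws tie-breaking is immaterial.
* `Sigma` proposals never leave the SPD cone (Wishart draws), and the
  density functions return $-\infty$ outside any support rather than
  erroring, so the sampler's accept/reject logic is total.
* A zero hierarchical sd is handled as a Dirac: the hierarchy density is 0
  (log scale) when the values match exactly and $-\infty$ otherwise.
* `sigma_rho = 0` pins every latent at its observed diameter and the model
  reduces to an ordinary hierarchical multivariate regression; a regression
  test asserts that log-posterior *differences* match the reduced model's.
* With only three species the among-species sds (and hence the global
  intervals) are weakly identified under their uniform priors; global
  credible intervals are correspondingly wide and heavy-tailed. This is a
  property of the design, not a convergence failure.
* Problem sizes used by the test suite: the desk-scale protocol (3 × 6,000
  iterations) for the headline fit and calibration checks, 20 single-chain
  replicates of the same length for interval coverage, 10,000-row residual
  matrices for the Wishart oracle, and 1,000 random topologies for the
  aggregation oracle.

```{r example, eval = FALSE}
fx <- study_fixture(seed = 7)
fit <- allom_hb(fx$observations, seed = 7)
summary(fit)
allom_ppc(fit, n_replicates = 500, seed = 1)
compare_scaling_models(fit)
```
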