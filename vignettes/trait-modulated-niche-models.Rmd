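---
title: "Trait-modulated Gaussian logistic niche models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-modulated Gaussian logistic niche models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichemod)
```

## The model

`nichemod` fits a hierarchical Bayesian unimodal response model to a binary
sites-by-species community table. Species `j` occurs at site `i` with
probability `p_ij`, where

    logit(p_ij) = a_j - (x_i - opt_j)^2 / (2 tol_j^2) + eps_i

so each species has a bell-shaped (Gaussian logistic) response along the
environmental gradient `x`: `opt_j` is the niche optimum (the gradient value
where occurrence is most likely), `tol_j > 0` the niche tolerance (curve
width), and `a_j` the logit of the occurrence probability at the optimum
(`p_max = plogis(a_j)`). `eps_i` is a Gaussian random site effect absorbing
residual correlation among species observed at the same site.

The ecological question is whether differences among species' niches can be
explained by their traits. Each niche parameter is therefore regressed on the
`m x K` trait table `Z`:

    opt_j      = mu_opt  + sum_k beta_opt_k  z_jk + u_j,   u_j ~ N(0, s2_opt)
    log tol_j  = mu_tol  + sum_k beta_tol_k  z_jk + v_j,   v_j ~ N(0, s2_tol)
    a_j        = mu_a    + sum_k beta_a_k    z_jk + w_j,   w_j ~ N(0, s2_a)

These are random-effect submodels: traits shift the species-level means but
species keep their own residual deviations, so including traits never
constrains a species' niche, it only moves unexplained variance from the
residual terms into trait effects.

### The tolerance submodel acts on the log scale

A literal linear submodel for `tol_j` does not force positivity. The package
models `log tol_j` linearly by default, which keeps every sampled state valid
and makes the random-walk updates well behaved. The residual variance of the
tolerance submodel is consequently reported on the log-tolerance scale
(parameter name `ltol`), and explained-variance fractions for the tolerance
compare log-scale variances. A strict linear-in-tolerance mode with
truncation at zero exists for density evaluation (`log_joint(...,
tol_model = "truncated")`) so the two parameterizations can be compared on
fixed states; the sampler itself uses the log parameterization, whose
hyperparameter updates remain exact Gibbs draws.

### Priors and variable selection

Intercepts get Uniform(-100, 100) priors and every standard deviation a
Uniform(0, 100) prior; these bounds are configurable in [mcmc_options()] and
are deliberately far from any plausible posterior mass on standardized data.
Trait slopes carry a spike-and-slab mixture: with prior probability 1/2
(a Bernoulli(0.5) indicator `gamma`) a slope is exactly zero, otherwise it
follows a double-exponential (Laplace) slab `lambda/2 * exp(-lambda |beta|)`,
whose heavy tails accommodate large coefficients better than a normal slab.
The slab rate `lambda` gets a Gamma(1, 1) hyperprior (one rate shared by the
three submodels; a fixed rate is available). The posterior mean of each
indicator is the variable's inclusion probability
([inclusion_probabilities()]). A plain normal prior on the slopes
(`prior = "normal"`, with its own uniform-sd hyperprior per submodel) is
provided as the non-sparse reference, matching the usual shrinkage
comparison.

All variances in this package are variances, never precisions.

## Sampling

The sampler is a bespoke blocked random-walk-within-Gibbs scheme:

* species niche parameters (`opt`, `log tol`, `a`) move by random-walk
  Metropolis, vectorized across species (given the site effects, species are
  conditionally independent);
* site effects move by random-walk Metropolis vectorized across sites;
* submodel intercepts are exact Gibbs draws (truncated normal);
* slope/indicator pairs are drawn jointly and exactly: conditional on the
  latent niche parameters the submodel is a Gaussian linear regression, so
  the Laplace-slab marginal likelihood is a closed-form normal-Laplace
  convolution and the slab draw is a two-piece truncated normal. Zero slopes
  are exactly zero in every draw — sparsity is structural, not numerical;
* residual variances, the site-effect variance and the slab rate are exact
  Gibbs draws (scaled inverse-chi-square under the uniform-sd prior, with
  rejection at the bound; Gamma for the rate).

Proposal scales adapt toward a 0.44 acceptance rate during burn-in only and
are frozen afterwards, so the retained chain is Markovian. Per-block
acceptance rates are recorded on every fit and a block with zero post-burn-in
acceptance raises a warning. Defaults follow common practice for this model
class: 10,000 iterations, the first half discarded as burn-in, three chains
with overdispersed starts. Identical seeds reproduce draws bit for bit.

### Starting values

Nonlinear hierarchical samplers need sensible starts. For each species the
quadratic-logit GLM `logit(p) = b0 + b1 x + b2 x^2` is fitted by maximum
likelihood and mapped to niche parameters by the closed-form
reparameterization `opt = -b1/(2 b2)`, `tol = 1/sqrt(-2 b2)`,
`a = b0 - b1^2/(4 b2)` (valid when `b2 < 0`; these estimates coincide with
direct nonlinear ML). A species whose optimum lies near or beyond the edge of
the sampled gradient looks monotone and yields `b2 >= 0`; such truncated
curves are handled by augmenting the species' data with artificial absences
outside the observed range (default: 25 zeros per side on a uniform grid
extending the range by one range-width per side — the defaults are
configurable and recorded in the init bundle). Augmentation affects starting
values only; the posterior always uses the original data. Species that fail
even after augmentation get neutral fallbacks (`opt = 0`, `tol = 1`, `a` from
prevalence) and are flagged. Submodel starts come from OLS of the GLM niche
estimates on the traits; the site-effect variance starts at 0.1.

### The latent environmental gradient

With several measured environmental variables, the gradient can be replaced
by a sparse linear combination `x_i = sum_l c_l env_il`, estimated jointly
with everything else using the same spike-and-slab machinery on the weights.
Two identifiability gauges must be fixed, because the response curve is
invariant to jointly rescaling (gradient, optimum, tolerance) and to jointly
flipping the sign of (gradient, optima):

* scale: reported weights are normalized to unit Euclidean norm; the
  spike-and-slab prior acts on the raw (pre-normalization) weights;
* sign: the weight of an anchor variable (by default the first) is kept
  non-negative; the flip is applied deterministically to every draw (weights,
  optima, and the optimum submodel's location parameters together), which is
  an exact symmetry of the posterior. Chains are therefore aligned by
  construction and cannot average over the two mirror modes.

Weights enter the likelihood nonlinearly, so they move by Metropolis:
one add/delete toggle per variable per iteration (a delete proposes exact
zero; an add proposes from a normal centred at zero, with the slab density in
the Hastings ratio) plus one joint random walk over the included weights.
Convergence in this mode is much slower than with a measured gradient — the
default run length for [fit_latent()] is 100,000 iterations (ten times the
plain default), and the examples below scale this down only because their
simulated signal is strong.

## Model comparison and summaries

[compute_dic()] reports both flavours of the deviance information criterion:
the classic effective parameter count `p_D = D_bar - D_hat` (deviance at the
posterior mean of the natural-scale parameters; posterior mean log-tolerance
is back-transformed first) and the variance-based estimator
`p_D = Var(D)/2`, using the within-chain sample variance (denominator
`n - 1`) averaged over chains. The classic `p_D` can be negative for
ill-behaved posteriors; it is flagged, never truncated, and both DIC variants
are always reported.

[variance_explained()] implements the explained-variance comparison: fit the
model with and without traits on identical data and compare the posterior
medians of the residual variances,
`100 (s2_without - s2_with) / s2_without` per niche parameter. The fraction
can be negative when traits cost more than they explain. The two fits are
fingerprint-checked to be on the same data.

[convergence_report()] computes split-R-hat and an
initial-positive-sequence effective sample size per scalar parameter —
standard, conservative choices; R-hat needs at least two chains.

Post-fit utilities mirror common ecological practice: [predict_curve()]
evaluates a species' response curve; [classify_groups()] splits species by
the sign of their posterior mean optimum (ties to group 2);
[trait_difference_tests()] compares the two groups trait by trait with
two-sided Wilcoxon rank-sum tests for continuous traits (exact by full
enumeration when both groups have at most 6 members and no ties, normal
approximation with tie correction otherwise) and chi-square tests on the 2x2
cross-tabulation for binary traits (no continuity correction by default —
both options are exposed and recorded). Tests act on the transformed
(standardized) trait values. No multiple-testing correction is applied.

## Data preparation

Inputs are three plain CSV tables (header row, ids in the first column):
occurrences (0/1), environment (sites x variables), traits (species x
traits). Missing cells may be empty fields or `NA`. The preprocessing rules
are:

1. impute missing cells ([simple_impute()]): column mean for continuous
   variables (taken on the log scale for log-flagged columns, matching the
   normality assumption that motivates the flag), column mode for binary
   traits with ties resolved to 0. This is a deliberately simple,
   deterministic single imputation; chained-equation multiple imputation is
   out of scope;
2. natural-log transform flagged environmental columns (flags are data
   metadata: columns whose raw distributions are clearly skewed), then centre
   and scale every environmental and trait column to mean 0, sd 1
   ([transform_and_standardize()]; `n - 1` sample sd — a convention choice).
   Binary traits are standardized like continuous ones; their kind is kept as
   metadata for the downstream tests;
3. drop species present in fewer than 5% of sites
   ([filter_rare_species()]).

Transformation parameters are retained, so [inverse_transform()] maps tables
back to the raw scale.

## A worked example

A small community simulated from the generative model (the same response
evaluator the likelihood uses), fitted with the spike-and-slab prior:

```{r example, eval = FALSE}
cfg <- synthetic_config(
  n = 200, m = 30, L = 1, K_cont = 4, K_bin = 0,
  mu = c(opt = 0, ltol = 0, a = 0.5),
  beta = list(opt = c(1.5, 0, 0, 0), ltol = rep(0, 4), a = rep(0, 4)),
  sigma_opt = 0.5, sigma_tol = 0.2, sigma_a = 0.5, sigma_site = 0.5,
  seed = 42)
sim <- simulate_community(cfg)

fit <- fit_niche(sim$occ, sim$truth$x, sim$traits,
                 mcmc_options(n_iter = 2000, n_chains = 1, seed = 7))
inclusion_probabilities(fit)
posterior_summary(fit, "^beta_opt")
```

Only the first trait (true slope 1.5) reaches an inclusion probability near
1; the null traits stay near or below the 0.5 prior level and their slopes
are exactly zero in the excluded draws.

## What the simulator does and does not emulate

[simulate_community()] draws traits (standard normal; binary traits Bernoulli
with prevalence 0.3 by default, then standardized like real data), niche
parameters from the submodels (tolerance on the log scale), Gaussian site
effects, and Bernoulli occurrences — exactly the fitted model, sharing its
response-curve code. [case_study_preset()] mimics the shape of a published
lake-phytoplankton survey (203 sites, 60 species, 11 environmental variables,
6 traits of mixed type) with a sparse two-variable-dominated latent gradient
and a binary trait that splits species into two niche groups; its effect
sizes are moderate so all species clear the 5% occupancy screen in typical
draws. A `"uniform"` gradient option produces optima near or beyond the
sampled range, exercising truncated response curves.

Passing calibration tests on these simulations shows the implementation is
faithful to its own model. Real community data violate the model in ways the
simulator deliberately does not reproduce — skewed or multimodal responses,
spatial autocorrelation, trait measurement error, non-random missingness —
so simulation results bound implementation error, not model misspecification.

## Numerical choices and limitations

* Initial GLM separation is detected and handled by a ridge-stabilized refit
  (small L2 penalty), flagged in the result rather than silent.
* Extreme augmented-GLM starting values are clamped to a sane band around the
  observed gradient before the chain starts; this touches initialization
  only.
* The site effects and the maximum coefficients trade off through a common
  additive constant; the Gaussian prior on the site effects soft-identifies
  this direction, which mostly shows up as slower mixing of `mu_a` and
  `sigma2_site`.
* Posterior means of chains that mix slowly (the latent mode especially)
  should be checked with [convergence_report()]; the package intentionally
  reports rather than hides poor mixing.
* Calibration studies in the test suite use scaled-down run lengths
  (hundreds to a few thousand kept draws, one or two chains, communities up
  to 200 x 40) chosen as the smallest sizes at which the checked properties
  are statistically decisive.
* Count responses (log link), multivariate quadratic response surfaces and
  multiple latent axes are out of scope.
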