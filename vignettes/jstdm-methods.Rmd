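---
title: "Joint species-trait distribution modelling with jstdm: model, priors and validation"
author: "jstdm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint species-trait distribution modelling with jstdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Community ecologists increasingly measure not only which species occur where
and how abundantly, but also how the traits of those species vary from site
to site.  `jstdm` fits a joint species-trait distribution model (JSTDM): a
hierarchical multivariate model in which every species contributes several
*column units* to one response matrix — its presence-absence (PA), its
abundance conditional on presence (ABUC), and one column per site-level
trait.  With $n_z$ response types and $n_s$ species the response matrix has
$n_s \times n_z$ columns; the tundra-shaped synthetic fixture shipped with
the package has $65 \times 5 = 325$.

For site $i$, species $j$ and response type $z$, the extended linear
predictor combines $n_c$ measured environmental predictors $x_{ik}$ with
$n_f$ latent factors $\eta_{ik}$:

$$L_{ijz} = \sum_k^{n_c} x_{ik}\,\beta_{kjz} + \sum_k^{n_f} \eta_{ik}\,\lambda_{kjz}.$$

PA columns are Bernoulli with a probit link on $L$; ABUC and trait columns
are log-normal — values enter the model on the natural-log scale with
Gaussian residuals.  Abundance is decomposed by a hurdle: ABUC is defined
(and a trait is measurable) only where the species is present, so those
cells are *structurally missing* where PA = 0.  Missing cells are
marginalised — they contribute to no likelihood term — which is exact under
conditional independence given the factors and avoids imputation
bookkeeping.

Two derived quantities carry most of the scientific content:

* **Associations.**  The loadings induce a covariance among column units,
  $\Omega_{j_1 z_1, j_2 z_2} = \sum_k \lambda_{k j_1 z_1}\lambda_{k j_2 z_2}$,
  which captures trait-abundance covariation beyond what the measured
  environment explains.  Under the intercept-only *null model* $\Omega$ holds
  the raw associations; under the *environmental model* the residual ones.
  `compareAssociations()` classifies entries as retained, explained-away or
  emergent between the two.
* **Trait-mediated responses.**  The expected response of column $(j, z)$ to
  predictor $k$ is modelled through species-level traits $t_{jl}$:
  $\mu_{kjz} = \sum_l t_{jl}\,\gamma_{klz}$.  The block expansion built by
  `expandTraitDesign()` makes the $\gamma_{klz}$ — specific to both predictor
  and response type — estimable within a single trait regression.

## Priors and the Gibbs sweep

The sampler is a blocked Gibbs sampler with full conjugate updates:

1. **Probit augmentation.**  Each observed PA cell carries a latent
   unit-variance normal truncated to $(0,\infty)$ for presences and
   $(-\infty,0]$ for absences (Albert–Chib).  The paper lineage names only
   the link; the augmentation is our implementation choice because it keeps
   every update exact.
2. **$(\Gamma, V, B)$ block.**  $\Gamma$ has a Gaussian prior
   $N(0, \texttt{gammaScale}^2 I)$ and a multivariate-normal full
   conditional; $V$, the covariance of the $\beta$ deviations from the
   trait-implied means, is inverse-Wishart with default
   $\mathrm{IW}(n_c + 1, I)$; each column's $\beta$ is a textbook Bayesian
   regression draw against the residualised (augmented) responses.
3. **Factors.**  Site scores have a standard-normal prior; loadings carry the
   multiplicative gamma process: local precisions
   $\psi_{hc} \sim \mathrm{Ga}(\nu/2, \nu/2)$ and column multipliers
   $\delta_1 \sim \mathrm{Ga}(a_1, b_1)$,
   $\delta_{h>1} \sim \mathrm{Ga}(a_2, b_2)$ with cumulative products
   $\tau_h = \prod_{m \le h}\delta_m$, so later factors are shrunk ever
   harder and a fixed factor budget (default `nFactors = 5`) behaves like an
   adaptive one.  Defaults $\nu = 3$, $a_1 = a_2 = 50$, $b_1 = b_2 = 1$
   mirror the published defaults of the hierarchical community-model
   lineage; every value is overridable in `jstdmPriors()`.
4. **Residual variances.**  Log-normal columns draw
   $\sigma_c^2 \sim \mathrm{InvGamma}$ (default shape 1, rate 0.1) over
   their observed cells; probit columns are pinned at 1.

The number of factors is fixed rather than born/killed adaptively —
reproducibility was worth more to us than the modest efficiency gain, and
the shrinkage prior makes surplus factors vanish in practice.  Factor signs
and ordering are left unidentified; every reported quantity ($\Omega$,
predictions, variance partitioning) is rotation-invariant, and
`convergenceDiagnostics()` therefore monitors $B$, $\Gamma$ and $\Omega$
entries but never loadings or scores individually.

**Scaling.**  Covariates and log-scale responses are centred and scaled to
unit variance by default.  The model lineage is silent on this; we scale
because the default priors are only sensible on a unit scale.  Both scalings
are recorded and invertible — `posteriorMean(fit, "Beta", scale = "data")`
returns coefficients on the original log-response/covariate scales, and all
predictions can be issued on the natural scale.  Zero or negative observed
trait values are hard errors rather than pseudo-counted: no pseudo-count is
part of the model, and silently fudging one would corrupt the log-normal
likelihood.  A trait value recorded where the species is absent violates
the hurdle data model and is likewise a hard error, with an explicit
`onInconsistentTrait = "mask"` escape hatch.

**Column ordering** is type-major (all PA units, then all ABUC, then each
trait), which makes $\Omega$ blocks directly comparable across response
types; `columnOrder()` provides the stable species-major permutation.

**RNG.**  One master seed spawns independent per-chain seeds, all recorded
in the fit object, so every stochastic result is bit-reproducible.  Chains
abort with the iteration index if a non-finite state is ever produced;
non-positive-definite conditional covariances raise errors rather than
being silently regularised.

## Prediction

`predictMarginal()` samples fresh factor scores from their prior per
posterior draw; PA columns map through $\Phi$, log-normal columns
back-transform as the predictive median $\exp(\cdot)$ by default (the
predictive mean $\exp(\cdot + s^2/2)$ and the raw log scale are available).
The median is the default because the headline validation metric — the
predictive correlation — is computed on the log scale, where the choice is
inert.

`predictConditional()` is the engine behind both conditional
cross-validation and scenario simulation: per posterior draw it runs a
short inner Gibbs sampler over the new sites' factor scores and the probit
latents of conditioned PA cells (default 50 sweeps after 20 discarded), and
averages the response-scale predictions over the retained sweeps, which
marginalises the scores over their conditional law.  Because the factor
scores' full conditional given fixed conditioning values is a fixed normal,
the inner chain mixes essentially immediately; the defaults were validated
against the closed-form bivariate-normal conditional (the package's
acceptance suite checks agreement within three Monte-Carlo standard
errors).  Sites sharing a conditioning pattern are updated as one
vectorised block.

`scenarioPredict()` composes the two: covariate overrides (explicit values,
or `"low"`/`"high"` for the 10%/90% reference-site quantiles — the
published scenario grids rarely print their values, so the engine takes
explicit ones rather than inventing numbers) plus fixed focal-species
column values, with everything unset marginalised.  Expected richness is
the sum of non-focal occurrence probabilities, averaged over reference
sites, with a posterior interval over draws.

## Cross-validation

`crossValidate()` partitions sites into near-equal folds and refits per
fold.  The training design is rebuilt from the training sites alone —
response and covariate scalings and derived species-level traits included —
so no information about held-out sites reaches the fold's model; the test
suite checks that baseline predictions of a held-out site are bit-identical
when that site's observed values are perturbed.  *Baseline* mode masks the
entire response vector of a test site; *conditional* mode conditions on
both hurdle components (PA, and ABUC where present) and predicts the trait
columns, since variation in presence is part of variation in abundance.
Predictive performance is the signed Pearson correlation between predicted
and observed values per species-trait combination, on the log scale
(invariant to the back-transform choice); combinations with fewer than
three pairs or zero-variance predictions are reported missing, not zero.
Species with zero presences in a training fold are dropped from that fold
with a warning.  CV refits default to reduced MCMC settings (4 chains of
4,000 iterations) with full-length overrides; settings are recorded on the
output.

## The synthetic-data generator

`generateParameters()` / `generateCommunity()` simulate from the exact
generative model: standard-normal covariates and factor scores, $\Gamma$ at
a stated effect scale, $B$ as trait-implied means plus deviations with
covariance $V$, loadings with per-factor scales halving in variance, then
the hurdle observation layer.  Covariates are independent standard normals
by design: the model, not the covariate climatology of any particular
landscape, is under test.  Abundance is positive continuous
(percent-cover-like), matching a log-normal ABUC likelihood, not integer
counts.  `caseStudyFixture()` produces a bundle with the case-study shape
(325 sites, 65 species, PA/ABUC/SLA/LA/MH, covariates GDD/FDD/SM) with
presence intercepts calibrated to prevalence targets spread evenly over
15–50% of sites — median near 0.3 and every species safely above the
25-site inclusion filter.

What passing tests on these data do **not** show: real communities have
correlated, non-Gaussian covariates, phylogenetic signal, spatial and
temporal autocorrelation, observation error in the traits, and integer or
semi-quantitative abundances.  None of those features are generated, and
the package deliberately fits none of them (no phylogenetic or
spatio-temporal random effects).

Site-level trait values are accepted as given.  Field protocols often
average a few individuals per species per site before analysis, and whether
that averaging happens on the natural or the log scale is usually
unreported; the package takes the supplied site-level value and applies its
own log transform, documenting rather than resolving that ambiguity.
Species-level traits are either supplied or derived as the mean of observed
log-scale site values.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: columns with no observed cells
draw their $\beta$ from the prior conditional; zero-variance response
columns fall back to centring without scaling; support for association
entries with zero posterior variance is reported as undefined rather than
0.5; correlation scaling is computed per draw and then averaged, so each
summand is a valid correlation matrix.  Truncated-normal draws use the
inverse-CDF with the uniform deviate clamped away from 0 and 1, so extreme
linear predictors cannot produce infinities.

The validation suite exercises the full pipeline at desk scale, chosen so
the whole suite runs in minutes: parameter recovery uses communities of 200
sites by 20 species with three response types and two factors (2 chains of
4,000 iterations); cross-validation checks use 100 sites by 8 species with
3 folds; the retention arithmetic of the production schedule (4 chains of
37,500 iterations, 12,500 burn-in, thinning 100) runs on a minimal
four-site design.  Larger problems are a matter of patience, not code
paths: the case-study-sized fixture (325 sites, 325 column units) fits with
the same functions.

## Known limitations

* No phylogenetic correlation structure, no spatial or temporal random
  effects, no GIS or microclimate preprocessing.
* Fixed factor count; adaptive truncation is a non-goal.
* The probit/log-normal family pair is the only one implemented; counts
  would need a different augmentation.
* Conditional prediction assumes the conditioning values are on the model's
  own scales (0/1 for PA, positive for log-normal units); it does not model
  observation error in the conditioning values.
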