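---
title: "Estimating context-dependent spatial and temporal co-occurrence from camera-trap data"
author: "coocc package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating context-dependent spatial and temporal co-occurrence from camera-trap data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coocc)
```

## Overview

`coocc` implements a three-stage analysis of how the species of an
assemblage co-occur in **space** and in **time**, and of which pair traits
explain both dimensions, across several survey areas ("contexts"):

1. a latent-variable **joint species distribution model** (JSDM) with
   imperfect detection, whose residual correlation matrix quantifies
   pairwise spatial co-occurrence beyond shared covariate responses;
2. **circular kernel density estimation** of diel activity, with pairwise
   activity-overlap coefficients and 95% activity isopleths quantifying
   temporal co-occurrence;
3. **species-pair regressions** (Gaussian identity-link for the bounded
   correlation response; beta regression for the overlap response) with
   full area interactions, relating both dimensions to dominance-hierarchy
   and ecological-similarity covariates.

A synthetic-data generator with known ground truth makes the whole
pipeline testable end to end without field data.

## The occupancy model

For species $i$ at camera site $j$ in one area, with $k_j$ active
trap-days:

$$z_{ij} = I(u_{ij} > 0), \qquad
u_{ij} = \beta_{0,i} + \beta_{1,i}\,\mathrm{TREE}_j + l_j\theta_i^\top +
\varepsilon_{ij},\qquad \varepsilon_{ij} \sim N(0, \sigma_i^2)$$

$$y_{ij} \sim \mathrm{Binomial}(k_j,\; z_{ij}\, p_{ij}), \qquad
\mathrm{logit}\, p_{ij} = \gamma_{0,i} + \gamma_{1,i}\,\mathrm{TRAIL\_W}_j
+ \gamma_{2,i}\,\mathrm{VEG\_D}_j$$

The $T$ latent site factors $l_j \sim N(0, I_T)$ and species loadings
$\theta_i$ absorb residual among-species dependence; the residual variance
is tied to the loadings by $\sigma_i^2 = 1 - \sum_t \theta_{it}^2$, so the
latent occupancy propensity $u_{ij}$ has unit residual-plus-factor
variance and

$$R = \theta\theta^\top + \mathrm{diag}(\sigma_1^2 \ldots \sigma_n^2)$$

is a correlation matrix: the **residual occupancy correlation**, the
spatial co-occurrence measure. All coefficients ($\beta$, $\gamma$) are
species-specific random effects from community-level normal
distributions. Covariates are standardized to mean 0, SD 1 *within each
area*; this standardization is part of the model definition, so any
subsetting of sites must be followed by an explicit `restandardize()` —
the fitting function refuses non-standardized covariates rather than
silently rescaling.

The number of latent factors defaults to $\lceil n/2 \rceil$ for $n$
species (`defaultFactorCount()`), which is enough to approximate an
$n$-species residual correlation matrix; it can be overridden per area in
the configuration (the built-in three-area setup uses 7/6/5 factors for
its 13/11/8-species assemblages, keeping 5 for the smallest assemblage
where the extra flexibility is cheap and mirrors common practice of not
dropping below ~5 factors).

### Sampler

Mixing a probit occupancy layer with a logit detection layer precludes a
single conjugate scheme, so `fitJSDM()` uses a purpose-built
Metropolis-within-Gibbs sampler (in compiled code):

* **z**: collapsed Bernoulli update with $u$ integrated out —
  $P(z_{ij}=1 \mid \cdot) \propto \Phi(m_{ij}/\sigma_i)(1-p_{ij})^{k_j}$
  against $1-\Phi(m_{ij}/\sigma_i)$ for cells with $y_{ij}=0$; cells with
  $y_{ij}>0$ are pinned at $z=1$ in every draw.
* **u**: truncated-normal draw given $z$ (naive rejection in the easy
  regime, shifted-exponential rejection in the tail).
* **$\beta_i$, $l_j$**: conjugate normal updates (the $l$ update shares
  one $T\times T$ precision factorization across sites).
* **$\theta_i$, $\gamma_i$**: random-walk Metropolis with step sizes
  adapted toward ~25% acceptance during burn-in only (frozen afterwards,
  so the post-burn-in chain is a valid MCMC). Proposals with
  $\sum_t\theta_{it}^2 > 1$ are rejected outright, keeping the
  $\sigma_i^2$ identity exact rather than renormalizing post hoc.
* **Identifiability**: $\theta$ is constrained lower-triangular with a
  positive diagonal during sampling. Only rotation-invariant quantities
  ($R$) are reported, so summaries never depend on this choice.
* **Hyperparameters**: community means get conjugate normal updates
  (prior $N(0, 2.25)$); community SDs get a log-scale random walk against
  a half-normal(1) prior. The model the published analysis cites does not
  print its priors, so these weakly-informative defaults are declared in
  `jsdmConfig()` and overridable.

Thinning is applied at storage time only, so the underlying chain
trajectory is independent of `thin`: doubling the thinning interval under
the same seed yields an exact subsample of the same draws. Each chain
draws from its own named substream of the master seed. Species never
detected in an area are dropped with a message before fitting.

Convergence is monitored with the potential scale reduction factor
$\sqrt{\hat V / W}$, $\hat V = \frac{n-1}{n}W + B/n$ (the plain
between/within form without sampling-variability corrections), over all
occupancy/detection coefficients and off-diagonal entries of $R$;
exceedances of 1.1 become a warning attached to the result.

### Summaries

`summarizeCorrelations()` reports, per species pair, the posterior mean,
central 95% credible interval, and the **sign probability** — the share
of draws sharing the posterior mean's sign. Sign probability > 0.9 is
classed as strong evidence of non-independence, with a secondary
"moderate" class above 0.7.

## Diel activity and temporal co-occurrence

Detections are reduced to **independent records**: within each (species,
site) stream, a record is kept only if it falls strictly more than one
hour (configurable) after the previously *kept* record — the sequential
chain rule used by camera-trap convention. The source analyses state the
rule only per species; scoping it per site is the stricter, conventional
reading and is what is implemented. Timestamps are converted to **solar
time** (longitude correction plus the equation of time, Spencer's
expansion, accurate to well under a minute), mapped to $[0, 2\pi)$ with
solar noon at $\pi$, so activity is measured against the sun rather than
the civil clock.

Each species' activity density is a von Mises kernel density estimate on
a 512-point angular grid (trapezoid quadrature error $<10^{-4}$ for
bandwidths up to ~50; the grid density is renormalized to integrate to
exactly 1). The smoothing bandwidth follows the plug-in von Mises rule

$$\kappa = \left[\frac{3 n \hat\kappa^2 I_2(2\hat\kappa)}
{4\sqrt{\pi}\, I_1(\hat\kappa)^2}\right]^{2/5}$$

with $\hat\kappa$ the maximum-likelihood concentration. When two species
are compared, the **larger** of their two bandwidths is used for both
(the alternative "most-smoothed = smaller $\kappa$" reading exists but is
not implemented). The exact bandwidth value is regression-locked in the
test suite and cross-checked against a least-squares cross-validation
optimum at the order-of-magnitude level.

The primary overlap estimator is the total-variation overlap

$$\Delta = 1 - \tfrac12 \oint |f - g| \, d\theta \in [0, 1],$$

0 for perfectly dissimilar and 1 for identical activity. A secondary,
*conditional* estimator — the mass of $f$ inside $g$'s 95% isopleth,
divided by 0.95 so self-overlap is exactly 1 — is available behind a
flag; it is directional in its arguments, and both are labelled in the
output because the legacy definition the published coefficients used
cannot be recovered exactly. The 95% **activity isopleth**
(`modalRegion()`) is the highest-density region: the smallest density
threshold whose exceedance set reaches 95% of the mass; its coverage can
overshoot the level by at most one grid cell's mass. Species with fewer
than 10 independent records (configurable) are excluded with a notice.

## Drivers of co-occurrence

`buildPairTable()` assembles one row per species pair per area where both
occur, with: dominance rank-pairing dummies (Apex = the apex predator;
Large > 20 kg; Medium 5–20 kg; Small < 5 kg; every pairing plus broad
Apex|Any and Large|Any contrasts), same-rank and same-family dummies,
diet overlap (shared food categories / unique categories of the pair),
and the body-mass ratio, defined larger/smaller so it is $\ge 1$ — the
one-sided scale on which the intermediate-ratio (quadratic) hypothesis is
expressible — together with its square. Rank pairings that cannot occur
in an area are recorded as structural zeros and dropped from designs.

Because the full set of rank pairings is too many covariates for one
model, `preselectDominance()` first fits one model per candidate (the
candidate interacting with area, nothing else) and keeps the
criterion-minimizing candidate; AIC is the default criterion (the
original selection procedure is in unpublished appendix material, so the
criterion is configurable). `collinearityScreen()` applies the |r| ≥ 0.7
rule: of a flagged covariate pair, the member with the higher
single-covariate $R^2$ for the response is retained, deterministically.

The **spatial** model is ordinary least squares on the full
area-interaction design (per-area intercepts and per-area slope blocks,
no pooled main effects — matching per-area coefficient columns); the
**temporal** model is maximum-likelihood beta regression (logit mean
link, constant precision $\phi$) with the boundary compression
$y' = (y(n-1) + 0.5)/n$ applied before fitting, so exact 0/1 overlaps are
admissible; interior observations move by less than $1/(2n)$. The BFGS
optimization uses the analytic score, and the reported fit carries the
maximum absolute score component at the optimum as a self-check. The
reported $R^2$ for the beta model is the Ferrari–Cribari-Neto pseudo-$R^2$
(squared correlation of linear predictor with link-transformed response),
labelled as such. Co-occurrence responses are treated as known
quantities: posterior uncertainty in the correlations is *not* propagated
into the driver regressions (a deliberate two-stage simplification, and a
documented limitation).

`compareContexts()` reports context-dependency for pairs present in two
or more areas: contrasting correlation signs across areas, and the share
of pairs whose activity overlap differs by at most 0.1 between areas.

## The synthetic-data generator

The generator emulates the surveyed system's structure: three adjacent
areas with 100/100/50 camera sites and assemblages of 13/11/8 carnivore
species (a built-in trait table of round literature body masses, families
and coarse diet sets), effort drawn from a truncated normal around
75 ± 15 trap-days (floor one day, rounded to whole days), community-
distributed occupancy and detection coefficients, $T$ latent site factors
inducing a known residual correlation matrix, binomial daily detections,
and species-specific diel densities. Choices the sources leave open are
declared here, once:

* **Covariates** are i.i.d. standard normal before within-area
  standardization (no spatial autocorrelation); the model only ever sees
  the standardized values.
* **Community hyperparameters** default to a moderately detectable guild:
  marginal occupancy ≈ 0.3–0.5 and daily detection ≈ 0.1 at an average
  site (`defaultHyperparams()`).
* **Loadings** are drawn from scaled normals; rows that would leave the
  unit ball are shrunk to a squared norm of 0.95 (not 1, so every species
  keeps positive residual variance) and flagged.
* **Diel activity** ground truth is a von Mises mixture per species —
  nocturnal, diurnal, crepuscular (dawn/dusk bimodal) or cathemeral —
  assigned as a deterministic function of the species name, so a species
  keeps its activity in every area (activity as an endogenous species
  property). A configurable fraction of records receives a follow-up
  within the hour to exercise the independence filter.
* **Seeds**: one master seed expands into named substreams (sites,
  community, occupancy, records, jsdm, drivers), so each stage is
  independently reproducible.

What the generator does *not* emulate — spatially autocorrelated
covariates, heterogeneous detection within a deployment, unmodelled
occupancy covariates, species misidentification — bounds what passing
tests show: they validate the estimators against their own generative
assumptions, not against every failure mode of real camera-trap data.

## Numerical choices and problem sizes

* KDE grid 512; quadrature is the rectangle rule on the uniform circular
  grid (exact for the renormalization; $<10^{-4}$ error at the
  bandwidths used).
* Truncated-normal sampling switches from naive rejection to Robert's
  shifted-exponential rejection at 0.4 SD into the tail.
* Zero-resultant activity samples (no directional signal) return the
  smallest positive bandwidth 0.01 with a warning rather than failing.
* Beta-regression starting values come from OLS on the link scale; SEs
  from the inverse observed information, reported as NA when the
  information matrix is numerically singular.
* The validation suite exercises the sampler at a scaled-down size chosen
  to be informative per unit time — 8 species, 300 sites, 60 trap-days,
  T = 2, 3 chains × 3000 retained iterations after 1000 burn-in — and the
  full three-area pipeline at 60/60/40 sites with shortened chains; the
  full-size configuration (100/100/50 sites, 3 × 30000 iterations after
  10000 burn-in, thinned by 10) is `defaultRunConfig()`.

## Known limitations

* Posterior uncertainty of stage-1/2 estimates is not propagated into the
  driver regressions.
* The conditional overlap estimator is directional; only the
  total-variation estimator is symmetric.
* Partitioning data by area underestimates co-occurrence strength
  relative to a joint multi-area model; area-specific fits are the
  intended design here.
* No goodness-of-fit assessment beyond convergence diagnostics; no model
  selection over occupancy covariates.
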