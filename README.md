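# coocc

Context-dependent spatial and temporal co-occurrence within animal
assemblages surveyed by camera traps.

Camera-trap studies of species-rich guilds (the motivating system is a
multi-area South African carnivore landscape) ask two linked questions:
do species share **space** beyond what their habitat preferences explain,
do they share **time** over the 24-h cycle — and do the answers change
with the management context? `coocc` implements the full analysis chain
for these questions, plus a ground-truth synthetic-data generator so
every stage can be validated without field data.

## What it computes

**Spatial co-occurrence** — a latent-variable joint species distribution
model with imperfect detection, fitted per area by a purpose-built
Metropolis-within-Gibbs sampler:

    z_ij = I(u_ij > 0),   u_ij = β0_i + β1_i·TREE_j + l_j·θ_iᵀ + ε_ij,
    ε_ij ~ N(0, σ_i²),    σ_i² = 1 − Σ_t θ_it²
    y_ij ~ Binomial(k_j, z_ij·p_ij),
    logit p_ij = γ0_i + γ1_i·TRAIL_W_j + γ2_i·VEG_D_j

with community random effects on β and γ. The residual occupancy
correlation matrix `R = θθᵀ + diag(σ²)` is the spatial co-occurrence
measure, summarized per pair by posterior mean, 95% credible interval,
and sign probability (>0.9 = strong evidence of non-independence).

**Temporal co-occurrence** — von Mises circular kernel density estimates
of diel activity in solar time (plug-in bandwidth; the larger of a pair's
bandwidths when comparing), total-variation overlap
`Δ = 1 − ½∮|f − g|` in [0,1], and 95% highest-density activity
isopleths.

**Drivers** — species-pair trait regressions with full area
interactions: Gaussian identity-link OLS for the correlation response,
maximum-likelihood beta regression (logit link, constant precision,
boundary compression) for the overlap response; dominance-hierarchy
covariate preselection by AIC, a |r| ≥ 0.7 collinearity screen, and a
context-dependency report for pairs shared across areas.

See `vignettes/cooccurrence-methods.Rmd` for the model details, sampler,
numerical choices and limitations.

## Worked example

A small two-area synthetic run (seven and five species, short chains;
the full-size study configuration is `defaultRunConfig()`):

```r
library(coocc)
tr  <- defaultTraitTable()
cfg <- defaultRunConfig(seed = 42)
cfg$areas <- list(
  PA = list(n_sites = 60, assemblage = tr$species[c(1, 2, 3, 7, 10, 11, 13)], T = 3),
  GR = list(n_sites = 40, assemblage = tr$species[c(2, 3, 7, 10, 13)], T = 2))
cfg$mean_effort <- 40; cfg$sd_effort <- 8; cfg$n_records <- 60
cfg$jsdm <- list(n_chains = 3, n_iter = 1000, n_burn = 500, thin = 2)
run <- runPipeline(cfg)
writeLines(run$report$text)
```

```
Co-occurrence pipeline report
Species pairs per area: GR=10, PA=21 (total 31)

Assemblage-level residual occupancy correlation:
 area n_pairs         mean         sd pct_positive      median         q33
   GR      10  0.003610689 0.06432823     60.00000 0.009557792 -0.05119706
   PA      21 -0.017822750 0.19938156     57.14286 0.034729291 -0.08849677

Strong-evidence pairs (sign prob > 0.9): 4
 area             species_a             species_b       mean sign_prob
   PA        spotted_hyaena               leopard -0.3479674 0.9286667
   PA        spotted_hyaena white_tailed_mongoose -0.5503994 1.0000000
   PA               leopard   large_spotted_genet -0.3126034 0.9560000
   PA white_tailed_mongoose      slender_mongoose  0.2859538 0.9373333

Context-dependency: 40.0% contrasting-sign pairs; 90.0% overlap diffs <= 0.1 (n shared = 10)

Truth recovery (synthetic run):
 area    rmse_R     cor_R
   PA 0.2332096 0.5641495
   GR 0.1530107 0.5637877
```

Reading this: each area's pairs are summarized by the mean and spread of
their residual occupancy correlations (near zero on average — species
mostly distribute independently); four pairs show strong evidence of
spatial dependence (sign probability above 0.9); 90% of shared pairs keep
their activity overlap within 0.1 across areas (diel activity behaves as
a species property); and because the data are synthetic, the report
appends how well the estimated correlation matrices recover the
generator's truth.

The stages are also available individually: `simulateSites()` /
`simulateCommunity()` / `simulateDetectionData()` / `simulateRecords()`
(generation), `filterIndependent()` / `toSolarTime()` /
`buildDetectionData()` (preparation), `fitJSDM()` /
`summarizeCorrelations()` (spatial), `selectBandwidth()` /
`circularKDE()` / `modalRegion()` / `pairwiseOverlap()` (temporal),
`buildPairTable()` / `preselectDominance()` / `fitSpatialGLM()` /
`fitBetaRegression()` / `compareContexts()` (drivers). All file I/O is
plain CSV/JSON.

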