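---
title: "Space-time CAR modelling of areal count panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-time CAR modelling of areal count panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stcar)
```

## The model

`stcar` fits a Bayesian Poisson lognormal model to a complete panel of
event counts $y_{it}$ observed in areas $i = 1, \dots, N$ over years
$t = 1, \dots, T$:

$$y_{it} \sim \text{Poisson}(\mu_{it}), \qquad
\log \mu_{it} = \alpha + X_{it}\beta + \phi_i + \xi_t + \delta_{it}.$$

The four latent pieces play distinct roles:

* $\phi_i$ is a spatially structured residual with an intrinsic
  conditional autoregressive (ICAR) prior: conditionally,
  $\phi_i \mid \phi_{-i} \sim N\!\big(\tfrac{1}{n_i}\sum_{j \sim i}
  \phi_j,\; \sigma^2_\phi / n_i\big)$, where $j \sim i$ ranges over the
  $n_i$ areas sharing a border with $i$. It absorbs unmeasured risk
  factors that vary smoothly in space.
* $\xi_t$ is a first-order random walk (RW1),
  $\xi_t \mid \xi_{t-1} \sim N(\xi_{t-1}, \sigma^2_\xi)$, describing the
  national time trend common to all areas.
* $\delta_{it}$ is a space-time interaction: an independent RW1 *per
  area*, $\delta_{it} \sim N(\delta_{i,t-1}, \sigma^2_\delta)$, letting
  each area's trend bend away from the national one smoothly in time but
  independently across space.
* $\alpha$ carries the overall level ($e^\alpha$ is the expected count
  for an average area-year at covariate means) and $\beta$ the covariate
  effects.

Priors follow standard weakly-informative disease-mapping practice:
Gamma(0.5, 0.005) on each precision $1/\sigma^2$, a flat prior on
$\alpha$, and $N(0, 1000)$ on each coefficient. Covariates are centred
at their grand mean over all $N \times T$ cells
(`center_covariates()`), which decorrelates them from $\alpha$ and is
the convention under which $e^\alpha$ is interpretable; a per-year
centring would instead fold part of the national trend into the
covariate means.

## Identifiability and constraints

The ICAR and RW1 priors are improper: both are invariant to a constant
shift, which a flat-prior intercept would otherwise absorb ad
infinitum. The sampler therefore imposes

* $\sum_i \phi_i = 0$, by recentring the field after each sweep and
  adding the removed mean to $\alpha$ — an exact move, because shifting
  all $\phi_i$ down and $\alpha$ up by the same amount changes neither
  the likelihood nor any prior density (the posterior is flat along that
  direction). The same recentring handles $\xi$. On a disconnected map
  the constraint is a single global one: per-component levels are
  identified by the likelihood, and only the overall level is confounded
  with $\alpha$. Maps with isolated areas are handled by giving those
  areas an exchangeable $N(0, \sigma^2_\phi)$ prior; recentring is then
  skipped (the shift direction is no longer prior-invariant) and the
  model remains proper.
* $\sum_t \delta_{it} = 0$ for every area $i$. This one is part of the
  model, not bookkeeping: an unconstrained per-area RW1 is flat in its
  level, so area levels would drain out of $\phi$ into $\delta$ and the
  spatial field would be entirely unidentified. The interaction prior is
  therefore the RW1 *conditioned on the row constraint* (a proper
  singular Gaussian of rank $T - 1$ per row), and the sampler never
  leaves that subspace: each Metropolis proposal perturbs one cell by
  $e$ and the whole row by $-e/T$. Column means of $\delta$ remain
  weakly confounded with $\xi$; both priors curve that direction, so the
  posterior is proper, and the model does not doubly-constrain it.

## Sampling

`run_mcmc()` runs independent Metropolis-within-Gibbs chains (compiled
core, R-level orchestration):

* $(\alpha, \beta)$ jointly, by random-walk Metropolis with a
  multivariate normal proposal shaped by the Cholesky factor of the
  maximum-likelihood Poisson regression covariance — the likelihood
  dominates these parameters, so the GLM geometry is nearly the
  posterior geometry and the block mixes in a few draws. A diagonal
  fallback covers degenerate panels.
* $\phi_i$ and $\xi_t$ by single-site random-walk Metropolis, and
  $\delta$ rows by the subspace proposals above.
* precisions by conjugate Gibbs:
  $1/\sigma^2_\phi \sim \Gamma(0.5 + \text{rank}/2,\; 0.005 +
  \phi^\top (D - W)\phi / 2)$ with rank $N - c$ ($c$ connected
  components; isolated areas add $\phi_i^2$ and one rank unit), and the
  RW1 analogues with ranks $T - 1$ and $N(T - 1)$.

Proposal scales adapt only during burn-in (Robbins-Monro on the log
scale, batches of 50), targeting 44% acceptance for single-site blocks
and 30% for the joint block; retained draws come from a fixed kernel.
Chains start over-dispersed: $\alpha$ at $\log \bar y$ plus noise,
fields at small jitter projected onto their constraints. Two numerical
guards: proposals pushing any $|\log \mu_{it}|$ beyond 30 are rejected
outright (a bound on the linear predictor far outside any plausible
state, preventing overflow mid-proposal), and precision draws are
floored at $10^{-12}$.

Defaults are production-scale — 4 chains, 20,000 burn-in iterations,
20,000 retained draws in total — while every knob is exposed through
`model_config()`. The validation studies in `tests/` use deliberately
smaller panels and shorter chains chosen so each check still has the
resolution it needs: the dense-grid oracle comparison uses a 2-area,
2-year panel (the largest on which 4-dimensional quadrature is exact for
practical purposes), replicate-recovery and model-comparison studies use
the 10×10-lattice fixture with single chains of a few thousand
iterations, and the convergence/calibration check uses 4 chains of 9,000
iterations, after which every split-chain PSRF of interest sits below
1.05.

## The synthetic-data generator

`simulate_panel()` is the package's test bed: it draws panels with
*exactly* the generative structure above and hands back the truth.
Its defaults are the study conditions the package is calibrated to:
$e^\alpha = 11.22$; six pre-centred standard-normal covariates with
coefficients $(0.11, 0.03, -0.55, 0.69, -0.01, 0.08)$ (the roles of
child population, unemployment-related claimants, vehicles per capita,
road density, walking/cycling prevalence, and school counts in the
motivating application); and variance components
$\sigma^2_\phi = 0.535$, $\sigma^2_\xi = 0.022$,
$\sigma^2_\delta = 0.004$. The default map is a rook-adjacent lattice
(`make_lattice_graph()`), whose degree distribution is a reasonable
stand-in for an administrative map. ICAR fields are drawn exactly via
the eigendecomposition of $D - W$ restricted to the sum-to-zero
subspace; RW1 paths are recentred to the same convention the sampler
uses — a mismatch there would silently bias every recovery test.

What the generator does **not** emulate: the marginal distributions of
real covariates (units, skew, temporal persistence), spatial correlation
*between* covariates and the latent field, boundary changes over time,
or overdispersion beyond the Poisson-lognormal structure. Passing
recovery tests therefore certify the inference machinery, not the
model's adequacy for any particular real dataset — that is what the
posterior predictive checks are for on real data.

## Posterior products

* **Marginal effects** (`marginal_effects()`): per draw,
  $\widehat{ME}_p = \overline{\mu} \cdot \beta_p$ with $\overline{\mu}$
  the fitted mean averaged over all $N \times T$ cells — the change in
  expected counts per unit covariate change, averaged over observations.
  (With a panel, "observations" means all cells, and coefficients are
  common across areas.)
* **Hotspots** (`hotspot_probability()`): $P(e^{\phi_i} > 1)$, the
  posterior probability that an area retains excess risk after covariate
  adjustment; areas above 0.9 are flagged.
* **Expected counts and extreme-area gaps** (`expected_counts()`): the
  yearly gap between the highest- and lowest-mean areas is computed per
  draw and then summarised, so its credible interval is a genuine
  posterior interval of the gap (the extremes may be attained by
  different areas in different draws; summarising means first would
  understate both the gap and its uncertainty — the package asserts this
  distinction in its tests).
* **Area trends** (`area_trend()`): each area's trend is
  $\xi_t + \delta_{it}$; the probability of exceeding the national trend
  is $P(\delta_{it} > 0)$, since the interaction *is* the
  area-minus-national difference under the additive decomposition. An
  exactly-zero draw counts one half, so a switched-off interaction
  yields the noncommittal 0.5 everywhere. This $\delta$-based reading is
  one of several possible exceedance constructions; a ratio of full
  fitted incidences would mix covariate and spatial contributions into
  what is meant to be a trend statement, so it is not the default.
* **Deprivation gradients** (`deprivation_gradient()`): per draw and
  year, the OLS slope of $\log \mu_{it}$ on the uncentred deprivation
  covariate across areas, with the between-year difference summarised —
  a widening slope means a widening socio-economic gap.

## Diagnostics

`gelman_rubin()` implements the split-chain potential scale reduction
factor $\sqrt{(n-1)/n + \frac{m+1}{m}\frac{B}{nW}}$ (each chain halved
first, which also detects within-chain drift; chains shorter than 4
cannot be split and are used whole). `waic()` computes
$-2(\text{lppd} - p_{\text{WAIC}})$ from pointwise posterior
log-likelihoods with a stabilised log-sum-exp, and
`competing_model_family()` fits the structural variants (no interaction,
iid instead of ICAR spatial, no spatial, no temporal) for WAIC ranking.

`bayesian_pvalue()` defaults to per-cell mid-p tail probabilities
$P(y^{\text{rep}} > y_{it}) + \tfrac12 P(y^{\text{rep}} = y_{it})$,
averaged over cells; the mid-p correction matters for discrete counts,
where the plain tail probability is biased above one half, and the
per-draw tail probabilities are computed analytically from the Poisson
distribution function rather than by sampling replicates, removing one
layer of Monte-Carlo noise. For data genuinely drawn from the fitted
model the average is 0.5 exactly in expectation. A global chi-square
discrepancy variant ($\sum (y - \mu)^2/\mu$ compared between replicates
and data) is exposed as an alternative; neither is claimed to be the
only reasonable posterior predictive statistic, which is why both are
labelled in the output.

## Known limitations

* $\sigma^2_\delta$ is weakly identified when small relative to the
  Poisson noise: at the calibrated conditions
  ($\sigma^2_\delta = 0.004$, means around 11) its posterior
  concentrates near 0.008 even for exact, very long chains — the
  Gamma(0.5, 0.005) prior and the interaction field's absorption of cell
  noise both push upward. The posterior tracks larger truths accurately
  (at $\sigma^2_\delta = 0.05$ it centres on 0.05), and the package's
  replicate studies treat the spatial variance, which is well
  identified, as the recovery benchmark.
* The interaction is independent across areas by design; spatially
  structured interactions (neighbouring areas sharing trend deviations)
  are out of scope.
* Single-site Metropolis on $\phi$ and $\delta$ is robust but not the
  fastest mixer; the slowest-mixing quantity in practice is
  $\sigma^2_\delta$, and chain lengths should be checked against its
  PSRF rather than the (much faster) fixed effects.
* Polygon-derived adjacency (`adjacency_from_polygons()`) requires
  topologically consistent GeoJSON boundaries: shared borders must be
  traced with the same vertices in both polygons (true of standard
  administrative boundary products). Areas touching at a single point
  are deliberately not neighbours (rook rule).

## A worked example

```{r example, eval = FALSE}
graph <- make_lattice_graph(10, 10)
sim <- simulate_panel(graph, T = 10, seed = 1)
cfg <- model_config(n_chains = 2, n_burnin = 4000, n_samples = 6000,
                    seed = 2)
fit <- run_mcmc(sim$panel, graph, cfg)
marginal_effects(fit, sim$panel)
hotspot_probability(fit)
waic(fit, sim$panel)$waic
```

The `analysis/` scripts run this workflow end to end at production
settings and write their tables under `results/analysis/`, and
`scripts/acceptance.R` condenses it into a single machine-readable
recovery report.
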