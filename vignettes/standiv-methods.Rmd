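---
title: "Methods: from tree inventories to diversity-productivity inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tree inventories to diversity-productivity inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`standiv` analyses planted tree-diversity experiments: networks of sites
where species are grown in monocultures and in mixtures along a species
richness gradient, in randomized blocks. This vignette documents the
models, the numerical conventions, and the design decisions behind the
package, and what the synthetic-data tests do and do not demonstrate.

## Productivity from inventories

Stand productivity is the annual basal-area increment per hectare
(m² ha⁻¹ yr⁻¹). Units are fixed package-wide: stem diameters in cm,
heights in m, areas in ha.

* Multi-stemmed trees are collapsed to the equivalent diameter
  `D = sqrt(sum(d_i^2))`. This is the unique single diameter whose basal
  area equals the summed per-stem basal areas, so per-tree aggregation and
  the plot-level basal-area sum commute.
* `tree_basal_area()` is `pi * (D/200)^2`; the constant 200 converts a cm
  diameter to an m radius.
* `plot_productivity()` sums live, in-sample trees, divides by the sampled
  fraction (plots inventoried on a subset of their area are scaled up
  proportionally), by plot area, and by stand age.
* Dead trees contribute zero by default: mortality lowers the live-tree
  sum. Whether trees that died before the final inventory should instead
  retain their last measured diameter is genuinely ambiguous in young
  experimental stands; `include_dead = TRUE` provides that alternative,
  and the choice only matters for plots with substantial mortality.
* `species_productivity()` is the same computation restricted to one
  species; by construction the species values sum exactly to the plot
  value, which the partition relies on.

## Diversity metrics

* **CWM**: abundance-weighted mean trait value. Abundance is the count of
  live trees at inventory by default (`weighting = "planted"` uses design
  counts); live counts reflect the realized community that actually
  produced the growth.
* **FDis**: abundance-weighted mean Euclidean distance of species to the
  abundance-weighted trait centroid. Species trait values are z-scored
  across experiments first, so traits with different units contribute
  comparably; Gower distances are unnecessary because all three traits
  (WD g cm⁻³, LNC %, SLA cm² g⁻¹) are quantitative. Monocultures have
  FDis 0 identically.
* **Structural diversity**: Gini coefficient and CV of individual tree
  heights. The Gini uses the population (n²) denominator with no
  small-sample correction; the CV uses the sample SD (n − 1). Both are
  relative (scale-free) metrics, and both choices only shift
  within-experiment standardized values by a constant factor. Heights
  come only from live trees with a measurement; plots with fewer than two
  measured heights get `NA` structural diversity and drop out of the SEM
  subset.
* **Trait PCA** (`trait_pca()`): correlation-matrix PCA of the species ×
  trait table, used to inspect the trait syndrome (a leaf-economics
  SLA–LNC axis roughly orthogonal to wood density). Degenerate inputs
  (zero-variance trait) are an error; fewer species than traits warns of
  rank deficiency.

## Standardization

Between-experiment differences (site quality, age, climate) dominate raw
variables, so continuous variables that vary within experiments are
standardized within experiment: z-scores for productivity, CWMs and
structural diversity; min–max scaling to [0, 1] for the FDis metrics.
Species-level trait values, which do not vary within experiments, are
z-scored across experiments. The diversity effects (NBE/SE/CE) are left
on the m² ha⁻¹ yr⁻¹ scale — they are already centered on each mixture's
own monocultures. Scaling is always recomputed on the analysis subset at
hand (`apply_scaling()` operates on the rows it is given); a z-score
computed on one subset is never reused on another. Degenerate groups
(zero SD or range) map to 0 with a warning rather than dropping plots.
Z-scores use the sample SD (n − 1).

## Additive partitioning

For a mixture of `N` species with observed per-species yields `Y_i`,
monoculture references `M_i` and planted proportions `p_i`:

```
dRY_i = Y_i / M_i - p_i
CE    = N * mean(dRY) * mean(M)
SE    = N * cov_pop(dRY, M)
NBE   = sum(Y_i) - sum(p_i * M_i) = SE + CE
```

The population covariance (divide by `N`) is the convention under which
the identity is exact, which the tests verify to 1e-10 on random inputs.
Monoculture references are the mean over a species' monoculture plots
pooled across blocks within the experiment (no block matching is
attempted — with typical replication, block-matched references would be
single plots and much noisier). Proportions come from planted counts by
default (`proportions = "surviving"` is available): the expectation is
defined by the design, and using realized survival would mix the
mortality response into the reference. Mixtures containing a species with
no (or a zero) monoculture reference are flagged `complete = FALSE` with
`NA` effects — never silently zero. Monocultures are excluded from the
partition by definition.

## Mixed models

All plot- and species-level models are Gaussian mixed models fitted by
maximum likelihood with `glmmTMB`. ML rather than REML so that AIC
comparisons across fixed-effect structures are valid. The shared random
structure is nested intercepts for species composition and block within
experiment, encoded as concatenated labels (`experiment:composition`,
`experiment:block`), so the grouping factors are plain independent
intercepts. The species-level model adds `experiment:class`
(angiosperm/gymnosperm).

The dispersion submodel lets the residual variance vary with species
richness: `Var(eps) = exp(delta0 + delta1 * richness)`. `glmmTMB`
parameterizes the Gaussian dispersion model on the log-SD scale
internally; `fit_lmm()` doubles those coefficients so that everything the
package reports is on the log-variance scale, and the tests verify the
scale by recovering a known simulated slope. p-values are two-tailed Wald
z tests as reported by `glmmTMB`; at the sample sizes of these designs
the difference from t-based intervals is negligible.

The species-level model fits `log(species productivity + c)`; `c`
defaults to half the smallest positive species productivity in the
analysis subset (the constant is stored on the fit object and
configurable). `h4_curve()` exposes fixed-effect richness curves
back-transformed with `exp(lp) - c`.

Degenerate fits: a failed optimizer run is an error carrying the
optimizer message; a non-positive-definite Hessian (typically a
random-effect variance collapsing to zero) is a warning and the fit is
retained, since the point estimates remain valid in that boundary case.

## Piecewise SEM

The DAG is: richness → structural diversity; richness → functional
dispersion; {richness, structural diversity, functional dispersion} →
productivity, optionally with one interaction term in the productivity
equation (`richness × structural` or `FDis × structural`). Each
endogenous variable gets its own mixed model with the shared random
structure and *constant* residual variance — a fixed variance is needed
for well-defined marginal R² values, computed as
`var(fixed predictions) / (var(fixed) + sum(random variances) +
residual variance)`.

The d-separation basis set contains one claim per non-adjacent variable
pair, conditioned on the union of the parents of both variables; for this
DAG that is the single claim *structural ⊥ FDis | richness*, giving
`df = 2`. Claims are tested by adding the claimed-independent predictor
to the mixed model of the claim's (topologically later) variable and
taking the two-tailed Wald p-value of its coefficient. Interaction terms
are derived quantities, not DAG nodes, and never enter conditioning sets.
Fisher's `C = -2 * sum(log p)` is referred to chi-squared with `2k` df;
with a single claim the SEM p-value equals the claim p-value exactly, a
fixed point the tests check. A claim p of exactly zero makes C infinite
and is flagged. Saturated DAGs have no claims and no C.

Standardized path coefficients are `beta * sd(x) / sd(y)` with SDs taken
from the analysis subset, so pre-standardized inputs pass through
unchanged; indirect effects are products of standardized coefficients
along directed routes. The Gini coefficient is the default structural
metric, with CV selectable; `fit_piecewise()` reports the summed
submodel AIC so the two can be compared.

## The synthetic generator

`generator_config()` / `generate_experiments()` emulate the *design* of a
young multi-site diversity experiment network, not forest dynamics:

* defaults: 9-year-old stands, 10 × 10 m plots of 25 planted trees
  (2500 stems ha⁻¹), species pools of 8, richness levels 1–6 with every
  pool species in monoculture, two mixtures per richness level, two
  blocks; trait syndrome with SLA–LNC correlation 0.68 and wood density
  nearly orthogonal, so the pooled trait PCA puts a leaf-economics axis
  first (a bit over half the variance) and a WD axis second.
* growth: per-tree annual diameter increment =
  species baseline × site × block × plot × mixing multiplier × lognormal
  noise, with the species baseline increasing in LNC and decreasing in WD.
  The acquisitiveness score `z(LNC) - z(WD)` summarizes that axis.
* the mixing multiplier
  `1 + (s * (acq_i - mean(acq_plot)) + k * FDis_plot) * (1 - exp(-(r-1)/tau))`
  saturates with richness and vanishes in monocultures. The selection
  term is centered within the plot — growth is reallocated toward the
  more acquisitive members — so `s` moves the covariance between relative
  yield deviations and monoculture productivity while leaving the mean
  deviation near zero; `k` lifts all members of functionally dispersed
  plots. Because yield scales with the squared diameter multiplier, an
  uncentered selection boost would mechanically inflate the
  complementarity component, which is why centering is needed to span
  selection-dominated regimes.
* mortality (10%), multi-stemmed trees (8%, stems splitting the squared
  diameter), a height allometry `h = 1.1 d^0.85` with lognormal noise,
  and a plot-level noise SD scaled by `exp(disp_slope * r / 2)` complete
  the data model. One random stream per experiment is derived from the
  master seed, so the network grows reproducibly.

Named scenarios fix the mixing regime: `null` (s = k = 0),
`selection` (s = 0.35), `complementarity` (k = 0.3), and `paper_like`
(s = 0.3, k = 0.015, 12 experiments, dispersion slope −0.03), the last
calibrated once so that realized selection shares across seeds fall in a
0.6–0.9 band, i.e. a clearly selection-dominated split of the net effect.
The truth record carries the noise-free expected NBE/SE/CE per mixture
(block and plot multipliers are omitted from the expectation: they are
mean-one and cancel across the design) and each scenario's tolerance
band.

What passing tests on generated data show — and what they do not: the
generator reproduces the *structure* of real inventories (nesting,
replication, monoculture references, trait-linked growth, saturating
mixing, mortality, multi-stem records) with known ground truth, so it
validates the computational chain end to end. It does not attempt
process-based realism: no climate, no spatially explicit competition, no
height-growth dynamics, no temporal trajectories. Results on generated
data say the machinery is correct, not that any particular ecological
effect size is realistic.

A further deliberate difference: in tree-level generated data, structural
diversity and functional dispersion are both driven by *which* species
are mixed, so the SEM's independence claim is genuinely violated there.
Calibration of Fisher's C is therefore assessed with
`simulate_sem_data()`, which draws plot-level data from the DAG itself
(and can inject a controlled violation through a shared latent variable);
`simulate_richness_data()` plays the same role for the quadratic richness
model, drawing directly from its equation with known coefficients and
dispersion slope.

## Problem sizes and numerical conventions

The simulation studies use sizes chosen to make Monte Carlo error small
relative to the margins being tested while keeping the default test run
fast: 100 replicates of 1500 plots across 20 experiments for
coefficient-recovery and dispersion-sign checks; 200 replicates of 300
plots for d-separation calibration (Kolmogorov–Smirnov test against
uniformity) and 50 replicates of 1000 plots for power against an injected
structural–functional dependence; 20 generator seeds for scenario-level
partition checks. Identity-type properties (partition additivity, oracle
equivalence of the diversity metrics) are tested to 1e-10 on hundreds of
random instances; floating-point identities (basal-area conservation,
idempotent scaling) to 1e-12.

## Known limitations

* Gaussian responses only; no crossed random effects; no bootstrap or
  simulation-based inference.
* The SEM machinery implements the recursive linear DAG used here, not
  general latent-variable or multigroup SEM; conditioning sets never
  contain interaction terms.
* Partition results are conditional on monoculture references estimated
  from the same experiment; experiments without monocultures for every
  mixed species yield flagged, incomplete partitions.
* The dispersion submodel is log-linear in richness; other variance
  structures are out of scope.
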