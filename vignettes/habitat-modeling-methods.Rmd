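---
title: "Methods: seabird habitat models and spatial prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seabird habitat models and spatial prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pelagicplan)
```

## The problem

Breeding seabirds on an offshore colony forage over a shelf system whose
value to them varies with surface-water properties, bathymetric setting and
ocean-climate state. `pelagicplan` is an analysis pipeline that goes from
binned strip-transect survey counts to (1) species-specific habitat-selection
models, (2) standardized habitat-use maps over a 1-km² prediction grid, and
(3) minimum-set conservation prioritization that can trade habitat value
against conflict with human activities. Every stage is driven by package
functions so the whole chain is testable; the `analysis/` scripts narrate one
full run.

Because long-term monitoring data of this kind are rarely releasable, the
package carries a first-class synthetic-data generator that emulates the
statistical structure of such a program — a multi-year series of cruises with
east-west transects, vessel-dependent strip widths, zero-inflated counts for
five focal species (a gull, a murre, two auklets, a cormorant), CTD stations,
monthly climate indices, and scored human-activity footprints.

## The count model

Counts in 3-km bins are modeled as a zero-inflated negative binomial (ZINB):

* count part: `mu = exp(x'beta + log A)`, where `A` is the surveyed bin area
  (km², length × strip width). The log-area exposure offset enters with its
  coefficient fixed at 1, so the model is an implicit density model that
  absorbs unequal bin lengths and strip widths.
* dispersion: NB2, `Var(y) = mu + alpha mu^2`, `alpha > 0`.
* zero inflation: structural-zero probability `pi = plogis(z'gamma)`, where
  `z` holds *detection-bias* covariates only (cloud cover, sea state, swell,
  visibility, time of day as numeric hhmmss). The reasoning: strip surveys
  assume full detectability inside the strip, but survey conditions produce
  false zeros; habitat covariates belong in the count part, observation
  conditions in the zero part.

Month and year enter the count part as categorical controls and are never
dropped by model selection. One species (the murre, abundant with few zero
bins) is modeled as a plain negative binomial; the Vuong comparison below
decides the family per species rather than assuming it.

### Fitting

The log-likelihood is the mixture density
`log(pi + (1-pi) NB(0))` for zeros and `log(1-pi) + log NB(y)` otherwise,
evaluated in log space. Maximization is BFGS with analytic gradients in
`(beta, gamma, log alpha)`, started from a `MASS::glm.nb` fit of the count
part and a logistic regression of the zero indicator (its intercept shifted
down, since the zero indicator overstates structural zeros). Failed starts
are retried with perturbations; non-convergence and apparent separation in
the inflation part are flagged on the fit object, never silent. Covariances
are numeric-Hessian based; the fit is cross-checked in the test suite
against `glmmTMB` on identical data.

Linear covariates are mean-centered before use and quadratic terms are the
square of the centered covariate — this reduces collinearity between a
covariate and its square and makes the intercept interpretable at the
covariate mean. Centering constants and factor levels are stored with the
fit so predictions on new cells use the training frame.

### Selection and diagnostics

1. **VIF screen**: every habitat covariate must have VIF < 10 against the
   others before entering the full model.
2. **Backward stepwise NB**, level 0.05: drop the worst-p term one at a
   time, reducing a quadratic to its linear form before the linear term can
   go; near-ties in p are resolved by refitting and dropping the term whose
   removal loses the least log-likelihood. Controls are untouchable.
3. **Detection terms**: the ZINB refit starts with all five detection-bias
   candidates in the inflation part and drops those with Wald p > 0.05.
4. **Family choice**: the Vuong statistic
   `V = sqrt(n) mean(m) / sd(m)` over per-observation log-density ratios
   `m_i` compares ZINB against plain NB; positive significant V keeps the
   zero-inflated family.
5. **Dispersion**: NB vs Poisson by likelihood ratio. Because `alpha` sits
   on the boundary of its space under the null, the reference distribution
   is the half-chi-square mixture (p = 0.5 at statistic 0) rather than a
   plain chi-square — a deliberate boundary correction.
6. **Interactions**: for each oceanographic covariate retained (SST, SSS,
   SSF), a year-by-covariate interaction is tested by likelihood ratio; the
   largest significant one is kept ("strongest interaction" rule).
7. **Validation**: 10-fold cross-validation; each bin is predicted exactly
   once from a fit excluding its fold, and the F test of observed counts
   regressed on out-of-fold predictions summarizes predictive skill. Fold
   assignment is seeded and recorded.

### A known limitation of the Vuong step

When the data are truly uninflated, ZINB and NB coincide on the boundary
`pi -> 0` and the models are nested rather than strictly non-nested; the V
statistic is then not asymptotically standard normal. Simulation with this
package's own fitter shows the one-sided 5% test is strongly conservative
with small inflation parts (≈0–1% null rejection with one detection
covariate) and anticonservative with larger ones (≈20% with three). The
package implements the classical statistic because it is the field's
standard model-preference tool in this setting, but treats it as a
preference heuristic, not a calibrated hypothesis test. The acceptance
suite records this behavior rather than hiding it.

## Surface interpolation

Per cruise and variable (SST, SSS, SSF), bin-midpoint values are
interpolated by ordinary kriging:

* empirical semivariogram: 12 lags to half the maximum pairwise distance,
  isotropic (no directional structure is modeled);
* candidate families exponential / spherical / gaussian, parameters by
  weighted least squares (pair-count over squared-model weights), with the
  range bounded below by the first lag distance — sub-lag ranges are
  indistinguishable from nugget and would leave the decomposition
  unidentified;
* family selection by leave-one-out cross-validation MSE of actual kriging
  predictions — a documented, testable stand-in for proprietary "parameter
  optimization" tooling with the same stated objective;
* a pure-nugget model is preferred whenever it cross-validates within 1% of
  the best structured model (parsimony on spatially unstructured data);
* prediction uses the 16 nearest neighbors, with weights constrained to sum
  to 1; nodes sharing a neighbor set are solved together. Duplicate data
  locations are averaged. Nodes farther than 25 km from any datum are
  flagged as extrapolated;
* surfaces whose leave-one-out RMSE exceeds the across-cruise mean + 2 SD
  are re-examined: a first-order trend surface is removed (and added back
  after kriging) when the trend diagnostic triggers — a significant plane F
  test at 0.05 or unbounded semivariogram growth at the largest lags. The
  "necessity" of detrending is subjective in practice; this trigger is the
  package's documented, testable proxy.

## Habitat maps

The prediction grid is 1-km² cells aligned to the region's minimum corner,
kept when the centroid falls inside the study region or a 5-km buffer
(centroids on the boundary count as inside). Cells carry kriged covariates,
distances computed exactly as for survey bins, the cruise's climate indices,
and detection-bias variables fixed at their modal observed values; exposure
is one cell (log A = 0).

Predicted abundance per cell is the mixture mean `(1 - pi) mu` (plain `mu`
for NB fits). Standardization divides each cruise layer by its cross-cell
mean, giving a relative-use index with mean exactly 1; monthly layers
average a month's cruises across years, and the across-months-and-years
layer is the mean of the monthly layers re-scaled to mean 1. Division by
the mean (rather than z-scoring, which is available behind a switch) keeps
amounts non-negative, which the prioritization targets require, and makes
the equal-contribution property exact: every species' final layer has grand
mean 1, so no species dominates the composite by sheer abundance. The
composite is the cellwise mean of species layers, displayed as percent
ranks `(rank-1)/(n-1)` with average ranks for ties, classed into deciles.

## Human-use cost layer

Six consolidated activities carry 1–5 impact scores (military 1, wildlife
viewing 2, benthic mobile-gear fishing 2, benthic fixed-gear fishing 3,
industrial shipping 4, oil/gas shipping 5; all overridable). A cell's score
is the sum over activities whose dominant-use polygon overlaps the cell
square — any shared area counts, not centroid containment, so corner-clipped
cells are costed. With all six defaults stacked the maximum is 17.

## Prioritization

The minimum-set problem: select cells minimizing
`sum(cost) + sum_f SPF_f * max(0, target_f - held_f)`, where features are
the species' standardized layers, targets are 10/30/50% of each feature
total, and SPF is the species penalty factor. Scenario 1 costs each cell 1
(area); scenario 2 costs `1 + human-use score`. Default SPFs are
`10 * max(total)/total_f`, so scarce species carry proportionally larger
shortfall penalties — an explicit operationalization of incentivizing
targets for the less abundant cormorant and auklet.

The solver is simulated annealing over single-cell add/remove moves
(compiled inner loop; R's RNG, so runs are reproducible from the seed):
initial temperature calibrated so ~80% of uphill moves would be accepted,
geometric cooling at 0.995, `10000 * max(1, n/100)` moves, then greedy
shortfall repair and redundancy pruning; the result is never worse than the
greedy-only construction, which is computed alongside. No
boundary-length/compactness penalty is applied (exposed for extension, off
by default). Ensembles run 100 independent seeded runs — selection
frequency per cell, the best solution, and the upper half of positive
frequencies for mapping. An exhaustive enumerator (≤ 20 units) is the
oracle the annealer is validated against.

## What the generator emulates — and what it does not

Defaults describe a 40 × 55 km coastal rectangle (≈2,200 km², the scale of
the emulated sanctuary system) with a mainland edge, a shelf-break isobath,
an island colony, and 27 cruises across 2004–2011 (April–September; May,
July and September every year). Surface fields are low-rank Gaussian random
fields (random Fourier features) with marginal means/SDs and hard min–max
clips set to survey-realistic values (e.g. SST 12.6 ± 1.62 °C in 8.9–16;
SSF is log-normal with CV ≈ 2 and is negatively coupled to the SST field so
the fluorescence gap-fill regression has real signal). Each field carries a
small (2%) micro-scale variance component below the bin spacing,
representing sub-bin water-mass structure and sensor noise; interpolation
correctly sees it as nugget, which is what puts leave-one-out RMSEs on a
realistic scale instead of near zero. Climate indices are clipped AR(1)
series; 11 of 27 cruises lack thermosalinograph fluorescence to exercise
the CTD gap-fill. True count models use per-SD coefficients whose signs
follow the qualitative habitat associations of the five species, with
intercepts calibrated once so marginal zero fractions match the species'
rarity profile (≈82/50/77/85/92% zero bins); the murre is generated from a
plain NB.

Not emulated: real bathymetry, currents or prey fields; geodesy (all
geometry is planar meters); distance-dependent detection (strip transects
assume full detectability in the strip); the true spatial clustering
process of sightings (group size is a free parameter, not a claim); and
activity frequency/effort weighting. Passing tests therefore demonstrate
the statistical machinery under a controlled generative model, not fidelity
to any particular real ecosystem.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: transects under 1 km produce no
bins (warned); identical field values give a degenerate variogram; all-zero
prediction surfaces are dropped from standardization with a warning;
duplicate kriging locations are averaged; infeasible prioritization targets
return their irreducible shortfall. Ties: sightings on a bin boundary go to
the earlier bin; stepwise p-ties drop the least-likelihood-loss term;
brute-force optimum ties prefer smaller then lexicographically earlier
sets.

The test suite exercises the full survey scale where the claim depends on
it — parameter recovery and interval coverage at n = 2,336 bins, test
calibration at n = 2,000 with 1,000 null replicates, all 81 cruise-variable
surfaces on a 50 × 50 grid, 100-run ensembles — and reduced fixtures (6
cruises, 3 transects of 14 km) elsewhere; these sizes are the package's
choices for a desk-scale, fully reproducible analysis.

## Known limitations

* The Vuong preference step is not a calibrated test under the uninflated
  null (see above).
* At very low mean abundance (expected counts well below 1 per bin with
  substantial inflation), the count intercept, inflation intercept and
  dispersion are only weakly jointly identified: their Wald intervals
  undercover (~86–90% at nominal 95% in this package's simulations, even at
  n = 10,000) while slope intervals stay calibrated. Interpret intercept
  inference for very sparse species with care.
* Kriging is isotropic with no co-kriging and no current-direction
  covariates; anisotropic flow structure would be mis-modeled.
* Month/year controls enter the count part only, not the inflation part.
* No uncertainty propagation from the fitted covariance into maps or
  prioritization amounts; maps are plug-in predictions.
* Extrapolated cells (beyond 25 km from data, or covariates beyond 3× the
  training range) are flagged but still predicted; interpret them with
  caution.
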