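# pelagicplan

Seabird habitat modeling and marine spatial prioritization from strip-transect
surveys.

Colonial seabirds concentrate their foraging in predictable parts of a shelf
system, and marine-sanctuary managers need to know where those places are and
how they overlap human activities. `pelagicplan` implements that analysis as
a tested pipeline for ecologists and conservation planners: from binned
at-sea survey counts, through species-specific count models and interpolated
surface-water fields, to standardized multi-species habitat maps and
minimum-set reserve selection under human-use costs. Because survey data of
this kind are usually not releasable, the package includes a first-class
synthetic-survey generator with the statistical structure the downstream
stages assume, so the entire chain runs — and is tested — end to end.

## The models at the core

**Counts.** Birds counted in 3-km transect bins, behavior-filtered to
foraging/feeding/sitting, are modeled as zero-inflated negative binomial:

    y_i ~ pi_i * delta_0 + (1 - pi_i) * NB(mu_i, alpha)
    mu_i = exp(x_i' beta + log A_i)        (A_i = surveyed area, offset fixed at 1)
    pi_i = logit^{-1}(z_i' gamma)          (z_i = detection-bias covariates)

with NB2 variance `mu + alpha mu^2`, habitat covariates (SST, SSS, SSF,
distances to land / 200-m isobath / colony, NPGO, PDO, SOI, upwelling index)
in the count part with linear-or-quadratic forms, and month/year as fixed
controls. Model selection is a VIF screen, backward stepwise elimination at
0.05, detection-term retention at 0.05, a Vuong comparison of ZINB vs plain
NB, a boundary-corrected likelihood-ratio test of overdispersion, selection
of one year × oceanography interaction by likelihood ratio, and 10-fold
cross-validation.

**Surfaces.** Per-cruise SST/SSS/SSF fields are interpolated by ordinary
kriging (isotropic semivariograms; exponential/spherical/gaussian candidates
fitted by weighted least squares, chosen by leave-one-out cross-validation;
first-order detrending when a documented trigger fires; 16-nearest-neighbor
prediction with weights summing to 1).

**Maps.** Per-cruise predictions on a 1-km² grid (5-km buffer) are divided by
their cross-cell mean (relative-use index, mean exactly 1), averaged within
month across years and then across months; species layers, each with grand
mean 1, combine into an equal-contribution composite displayed as percent
ranks and deciles.

**Prioritization.** Minimum-set reserve selection: minimize
`sum(cost) + sum_f SPF_f * shortfall_f` subject to holding 10/30/50% of each
species' standardized habitat. Scenario 1 costs cells by area; scenario 2 by
`1 + human-use score`, where the score sums 1–5 impact ratings of six
activity footprints (max 17). A simulated annealer (compiled inner loop,
greedy repair, redundancy pruning) is run 100 times per problem for selection
frequencies; an exhaustive oracle validates it on small instances.

## Worked example

```r
library(pelagicplan)

region <- default_region(6)              # 6 cruises at full spatial scale
sim    <- simulate_survey(sim_config(seed = 5), region)
mt     <- build_model_table(sim)
table(mt$table$WEGU == 0)
#> FALSE  TRUE
#>    93   411
# 411/504 = 81.5% zero bins for the gull, matching its configured rarity

spec <- model_spec("WEGU",
                   data.frame(var = c("dist_sefi", "dist_200", "ui"),
                              form = "linear"),
                   infl = "seastate", controls = "month")
fit <- fit_habitat_model(spec, mt$table)
nb  <- fit_habitat_model(spec, mt$table, family = "nb")
vuong_test(fit, nb)
#> Vuong test: statistic = 2.8334, p = 0.002303 (prefers zinb)
cross_validate(spec, mt$table, folds = 10, seed = 1)
#> CV-F test: statistic = 18.9391, p = 1.771e-05
```

The gull's zero-inflated model is preferred over plain NB (positive Vuong
statistic, p < 0.05) and out-of-fold predictions explain the observed
counts (CV F test). The full model-selection workflow
(`fit_species_workflow`: VIF screen, backward stepwise elimination,
detection-term retention, family choice, interactions, cross-validation)
needs the 27-cruise design — with only 6 cruises the cruise-level climate
indices are aliased with the month/year controls and the full model is
correctly refused as rank-deficient. The full analysis, including kriged
surfaces, habitat maps, the human-use layer and both prioritization
scenarios, is narrated by the numbered scripts:

```sh
Rscript analysis/01_simulate.R 1      # raw survey products under results/raw/
Rscript analysis/02_prepare.R         # 3-km model table
Rscript analysis/03_fit_models.R 1    # per-species workflows + coefficient table
Rscript analysis/04_krige_surfaces.R  # 81 kriged surfaces + RMSE summary
Rscript analysis/05_habitat_maps.R    # standardized + composite maps
Rscript analysis/06_human_use.R       # cost layer
Rscript analysis/07_prioritize.R 1    # scenarios 1-2 at 10/30/50% targets
```

Column layouts of every file are in `inst/extdata/data_dictionary.md`; the
modeling choices and their rationale are in
`vignettes/habitat-modeling-methods.Rmd`.

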