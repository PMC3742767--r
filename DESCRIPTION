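Package: pelagicplan
Title: Seabird Habitat Modeling and Marine Spatial Prioritization from Strip-Transect Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for modeling at-sea seabird habitat selection
    from binned strip-transect surveys and turning the fitted models into
    conservation-planning inputs. Includes a synthetic survey generator with
    realistic covariate structure; 3-km transect binning with exposure areas and
    gap-filled surface fluorescence; zero-inflated negative binomial habitat
    models with exposure offsets, detection-bias zero-inflation covariates,
    Vuong and boundary-corrected likelihood-ratio diagnostics, backward
    stepwise selection and n-fold cross-validation; per-cruise ordinary kriging
    of surface-water fields with automated variogram selection; standardized
    single- and multi-species habitat-selection maps on a 1-km2 prediction
    grid; a scored human-use cost layer; and minimum-set reserve selection by
    simulated annealing with selection frequencies across runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmmTMB,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
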