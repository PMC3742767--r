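# Per-species modeling workflow: multicollinearity screen, backward stepwise
# negative-binomial simplification, zero-inflated refit with detection-bias
# terms, year x oceanography interaction selection, model-preference tests
# and n-fold cross-validation.

#' Candidate habitat covariates and detection-bias variables
#' @return list with `habitat` (count-part candidates) and `detection`
#'   (inflation-part candidates).
#' @export
candidate_covariates <- function() {
  list(habitat = c("sst", "sss", "ssf", "dist_land", "dist_200", "dist_sefi",
                   "npgo", "pdo", "soi", "ui"),
       detection = c("cloud", "seastate", "swell_m", "visibility", "time"))
}

#' Run the full modeling workflow for one species
#'
#' Steps, in order: VIF screen of the habitat candidates (all must pass at
#' 10); backward stepwise negative-binomial simplification at the 0.05 level
#' starting from quadratic forms of every candidate (controlling for month
#' and year); zero-inflated refit with detection-bias covariates retained at
#' 0.05; Vuong test of the zero-inflated model against the plain negative
#' binomial — the preferred family is kept; dispersion LR test (NB over
#' Poisson); year-by-oceanography interaction selection by likelihood ratio;
#' and n-fold cross-validation of the final model.
#'
#' @param tab model table from [build_model_table()].
#' @param species species column to model.
#' @param level significance level used throughout.
#' @param folds cross-validation folds.
#' @param cv_seed seed for the fold assignment.
#' @return list: `spec` (final [model_spec()]), `fit` (final `habitat_fit`),
#'   `vif`, `vuong`, `lr_alpha`, `interaction_tests`, `cv`, `family`.
#' @export
fit_species_workflow <- function(tab, species, level = 0.05, folds = 10,
                                 cv_seed = 1L) {
  cand <- candidate_covariates()
  vif <- vif_screen(tab[, cand$habitat])
  if (!all(vif$pass))
    warning("covariates failing the VIF screen: ",
            paste(vif$variable[!vif$pass], collapse = ", "))
  keep <- vif$variable[vif$pass]
  full <- model_spec(species,
                     data.frame(var = keep, form = "quadratic"),
                     controls = c("month", "year"), family = "nb")
  step <- backward_stepwise(full, tab, level = level)
  spec_nb <- step$spec
  spec_nb$family <- "nb"
  nb_fit <- fit_habitat_model(spec_nb, tab, family = "nb")
  pois_fit <- fit_habitat_model(spec_nb, tab, family = "poisson")
  lr <- lr_test_alpha(nb_fit, pois_fit)

  spec_zi <- spec_nb
  spec_zi$family <- "zinb"
  spec_zi$infl <- cand$detection
  spec_zi <- select_detection_terms(spec_zi, tab, level = level)
  zi_fit <- fit_habitat_model(spec_zi, tab)
  vuong <- vuong_test(zi_fit, nb_fit)

  if (vuong$preferred == "zinb" && zi_fit$converged) {
    spec <- spec_zi
    fit <- zi_fit
  } else {
    spec <- spec_nb
    fit <- nb_fit
  }
  sel <- select_interaction(spec, tab, level = level)
  spec <- sel$spec
  if (!is.null(spec$interaction)) fit <- fit_habitat_model(spec, tab)
  cv <- cross_validate(spec, tab, folds = folds, seed = cv_seed)
  list(spec = spec, fit = fit, vif = vif, vuong = vuong, lr_alpha = lr,
       interaction_tests = sel$tests, cv = cv, family = spec$family)
}

#' Tidy coefficient table across species workflows
#'
#' One row per retained variable per species: best transformation (L/Q),
#' coefficient sign and Wald p-value — the layout used to summarize
#' habitat-selection models across species.
#'
#' @param workflows named list of [fit_species_workflow()] results.
#' @return data.frame `species`, `variable`, `form`, `sign`, `p`.
#' @export
coefficient_table <- function(workflows) {
  rows <- list()
  for (sp in names(workflows)) {
    wf <- workflows[[sp]]
    sm <- fit_summary(wf$fit)
    for (i in seq_len(nrow(wf$spec$count))) {
      v <- wf$spec$count$var[i]
      quad <- wf$spec$count$form[i] == "quadratic"
      col <- if (quad) paste0("I(", v, "^2)") else v
      est <- sm$estimate[sm$term == col]
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, variable = v, form = if (quad) "Q" else "L",
        sign = if (est >= 0) "+" else "-", p = sm$p[sm$term == col])
    }
    for (v in wf$spec$infl) {
      est <- sm$estimate[sm$term == paste0("zero_", v)]
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, variable = paste0("zero:", v), form = "L",
        sign = if (est >= 0) "+" else "-",
        p = sm$p[sm$term == paste0("zero_", v)])
    }
  }
  do.call(rbind, rows)
}

#' Predict, standardize and composite habitat maps for all species
#'
#' For each species and cruise, predicts expected abundance on the grid cells
#' at 1-km2 exposure from the species' final fit, standardizes within cruise
#' and across months and years, and combines species into the equal-
#' contribution multi-species composite with percent ranks.
#'
#' @param workflows named list of [fit_species_workflow()] results.
#' @param cells grid from [build_grid()].
#' @param suite kriged `surface_suite` covering every cruise.
#' @param tab model table (for indices and modal detection values).
#' @param calendar cruise calendar.
#' @return list: `species_maps` (named list of standardized overall vectors),
#'   `monthly` (per species), `composite` (data.frame with percent ranks and
#'   deciles).
#' @export
build_habitat_maps <- function(workflows, cells, suite, tab, calendar) {
  cruises <- calendar$cruise_id
  covs <- lapply(cruises, function(cid) cell_covariates(cells, suite, cid, tab))
  names(covs) <- cruises
  species_maps <- list(); monthly <- list()
  for (sp in names(workflows)) {
    pred <- vapply(cruises, function(cid) {
      predict_abundance(workflows[[sp]]$fit, covs[[cid]])$pred
    }, numeric(nrow(cells)))
    std <- standardize_predictions(pred, calendar)
    species_maps[[sp]] <- std$overall
    monthly[[sp]] <- std
  }
  list(species_maps = species_maps, monthly = monthly,
       composite = composite_multispecies(species_maps))
}
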