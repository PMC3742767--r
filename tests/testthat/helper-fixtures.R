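# Small fixtures built in code: a reduced study region and survey config so
# most tests run in seconds; full-scale conditions are exercised in the
# acceptance tests.

small_region <- function(n_cruises = 6) {
  boundary <- rbind(c(0, 0), c(20000, 0), c(20000, 24000), c(0, 24000))
  calendar <- expand.grid(month = c(5, 7, 9), year = c(2004, 2005))
  calendar <- calendar[seq_len(n_cruises), c("year", "month")]
  calendar$end_day <- 15L
  study_region(boundary,
               colony = c(13000, 10000),
               mainland = rbind(c(20000, -5000), c(20000, 29000)),
               isobath_200 = rbind(c(6000, -5000), c(6500, 12000), c(5800, 29000)),
               calendar = calendar)
}

small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_transects = 3L, transect_length_km = 14, ...)
}

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_survey(small_config(), small_region())
    cache
  }
})

# six cruises at the full spatial scale (the scale the default species truth
# is calibrated for)
default6_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_survey(sim_config(seed = 5),
                                                  default_region(6))
    cache
  }
})

small_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_model_table(small_sim())
    cache
  }
})

# simple bin table of iid covariates on the published scales, for model tests
synth_bins <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    sst = rnorm(n, 12.6, 1.62), sss = rnorm(n, 33.3, 0.48),
    dist_200 = runif(n, 23, 47260), dist_sefi = runif(n, 1273, 65366),
    cloud = round(runif(n, 0, 9)), seastate = round(runif(n, 0, 6)),
    visibility = round(runif(n, 0, 9)),
    month = sample(c(5, 7, 9), n, TRUE), year = sample(2004:2007, n, TRUE),
    area_km2 = runif(n, 0.3, 0.9))
}
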