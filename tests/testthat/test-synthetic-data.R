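# Generator: determinism, distributional fidelity to the published covariate
# summaries, and the ZINB count process against its closed forms.

test_that("environment fields are deterministic, in range, and track the configured mean", {
  region <- default_region()
  cfg <- sim_config(seed = 3)
  f1 <- generate_environment_fields(cfg, region)
  f2 <- generate_environment_fields(cfg, region)
  set.seed(99)
  pts <- cbind(runif(400, 0, 40000), runif(400, 0, 55000))
  expect_identical(field_eval(f1$C01$sst, pts), field_eval(f2$C01$sst, pts))

  # per-cruise means across all 27 cruises: mean of means within 3 SE of 12.6
  cruise_means <- vapply(f1, function(fl) mean(field_eval(fl$sst, pts)), 0)
  se <- sd(cruise_means) / sqrt(length(cruise_means))
  expect_lt(abs(mean(cruise_means) - 12.6), 3 * se)

  # all values within the reference min-max
  for (cid in names(f1)[1:5]) {
    for (v in c("sst", "sss", "ssf")) {
      vals <- field_eval(f1[[cid]][[v]], pts)
      sc <- pelagicplan:::covariate_scale[[v]]
      expect_true(all(vals >= sc$min & vals <= sc$max))
    }
  }
})

test_that("zero field SD gives a constant field at the mean", {
  region <- small_region()
  flds <- default_field_params()
  flds$sss$sd <- 0
  cfg <- small_config(fields = flds)
  f <- generate_environment_fields(cfg, region)
  pts <- cbind(runif(50, 0, 20000), runif(50, 0, 24000))
  expect_equal(field_eval(f$C01$sss, pts), rep(33.3, 50))
})

test_that("invalid spatial range is rejected", {
  flds <- default_field_params()
  flds$sst$range_m <- -1
  expect_error(small_config(fields = flds), "range")
})

test_that("covariate CV of generated fields is within 50% of the reference CV", {
  sim <- default6_sim()
  tab <- sim$survey$truth
  for (v in c("sst", "sss", "ssf")) {
    sc <- pelagicplan:::covariate_scale[[v]]
    cv_pub <- sc$sd / abs(sc$mean)
    cv_sim <- sd(tab[[v]]) / abs(mean(tab[[v]]))
    expect_lt(abs(cv_sim - cv_pub), 0.5 * cv_pub)
  }
})

test_that("survey records carry vessel-dependent strips and full condition set", {
  sim <- small_sim()
  eff <- sim$survey$effort
  expect_true(all(eff$strip_width_m >= 50 & eff$strip_width_m <= 300))
  # vessel rotation: Martin ~100 m
  martin <- eff[eff$vessel == "Martin", ]
  expect_true(all(martin$strip_width_m <= 100))
  expect_true(all(eff$seastate %in% 0:6))
  expect_true(all(eff$cloud %in% 0:9))
  expect_true(all(eff$visibility %in% 0:9))
  expect_true(all(eff$swell_m >= 0))
  expect_true(all(sim$survey$sightings$behavior %in%
                    c("flying", "foraging", "feeding", "sitting", "ship-attract")))
})

test_that("zero transects configured yields an empty record set without failure", {
  region <- small_region()
  cfg <- small_config(seed = 2)
  cfg$n_transects <- 0L
  fields <- generate_environment_fields(cfg, region)
  idx <- generate_climate_indices(cfg, region)
  sv <- generate_transect_survey(cfg, region, fields, idx)
  expect_equal(nrow(sv$effort), 0L)
  expect_equal(nrow(sv$sightings), 0L)
})

test_that("total structural inflation gives all-zero counts; dispersion must be positive", {
  bins <- synth_bins(200)
  truth_all0 <- list(SP = list(count = c(`(Intercept)` = 1, sst = 0.3),
                               infl = 1.0, alpha = 1))
  y <- generate_counts_zinb(truth_all0, bins, seed = 5)
  expect_true(all(y[, "SP"] == 0L))
  bad <- list(SP = list(count = c(`(Intercept)` = 1), infl = NULL, alpha = 0))
  expect_error(generate_counts_zinb(bad, bins, seed = 1), "alpha")
})

test_that("simulated counts match the analytic ZINB mean and zero fraction", {
  bins <- synth_bins(10000, seed = 7)
  truth <- list(count = c(`(Intercept)` = 0.6, sst = 0.4, dist_200 = -0.3),
                infl = c(`(Intercept)` = -0.4, cloud = -0.3), alpha = 1.5)
  y <- generate_counts_zinb(list(SP = truth), bins, seed = 11)[, "SP"]
  mom <- zinb_truth_moments(truth, bins)
  # mean within Monte-Carlo error (analytic per-bin variances summed)
  v <- (1 - mom$pi) * (mom$mu + truth$alpha * mom$mu^2) +
    mom$pi * (1 - mom$pi) * mom$mu^2
  se_mean <- sqrt(sum(v)) / length(y)
  expect_lt(abs(mean(y) - mean(mom$mean)), 4 * se_mean)
  # zero fraction within binomial band of the analytic value
  p0 <- mean(mom$p_zero)
  expect_lt(abs(mean(y == 0) - p0), 3 * sqrt(p0 * (1 - p0) / length(y)))
})

test_that("zero fraction matches pi + (1-pi) NB(0) for random coefficient draws", {
  bins <- synth_bins(4000, seed = 3)
  set.seed(21)
  for (k in 1:20) {
    truth <- list(count = c(`(Intercept)` = runif(1, -1, 1.5),
                            sst = runif(1, -0.5, 0.5)),
                  infl = c(`(Intercept)` = runif(1, -1.5, 1),
                           cloud = runif(1, -0.5, 0.5)),
                  alpha = runif(1, 0.3, 4))
    y <- generate_counts_zinb(list(SP = truth), bins,
                              seed = sample.int(1e6, 1))[, "SP"]
    mom <- zinb_truth_moments(truth, bins)
    p0 <- mean(mom$p_zero)
    se <- sqrt(mean(mom$p_zero * (1 - mom$p_zero)) / nrow(bins))
    expect_lt(abs(mean(y == 0) - p0), 3.5 * se)
  }
})

test_that("empirical zero fraction increases with the inflation probability", {
  bins <- synth_bins(4000, seed = 5)
  zf <- vapply(c(0, 0.3, 0.6, 0.9), function(p) {
    truth <- list(SP = list(count = c(`(Intercept)` = 0.8, sst = 0.3),
                            infl = p, alpha = 1))
    mean(generate_counts_zinb(truth, bins, seed = 17)[, "SP"] == 0)
  }, 0)
  expect_true(all(diff(zf) > 0))
})

test_that("default species truth reproduces the reference zero fractions", {
  sim <- default6_sim()
  tab <- sim$survey$truth
  published <- c(WEGU = 1918, COMU = 1172, CAAU = 1809, RHAU = 1995,
                 BRAC = 2158) / 2336
  for (sp in names(published)) {
    expect_lt(abs(mean(tab[[sp]] == 0) - published[[sp]]), 0.06)
  }
})

test_that("CTD stations: 15-18 per cruise, surface value tracks the field, containment enforced", {
  sim <- small_sim()
  counts <- table(sim$ctd$cruise_id)
  expect_true(all(counts >= 15 & counts <= 18))
  # zero-noise config reproduces the field exactly
  region <- small_region()
  cfg <- small_config(seed = 4, ctd_noise_sd = 0)
  f <- generate_environment_fields(cfg, region)
  ctd <- generate_ctd_stations(cfg, region, f)
  c1 <- ctd[ctd$cruise_id == "C01", ]
  expect_equal(c1$ssf_1_6m,
               field_eval(f$C01$ssf, cbind(c1$x, c1$y)), tolerance = 1e-12)
  expect_error(
    generate_ctd_stations(cfg, region, f,
                          stations = rbind(c(-5000, 5000), matrix(5000, 17, 2))),
    "inside")
})

test_that("activity footprints: six named activities with published scores", {
  region <- small_region()
  acts <- generate_human_activities(region)
  expect_length(acts, 6L)
  expect_setequal(vapply(acts, `[[`, "", "activity"),
                  c("military", "wildlife_viewing", "benthic_mobile_gear",
                    "benthic_fixed_gear", "industrial_shipping",
                    "oil_gas_shipping"))
  expect_equal(acts$industrial_shipping$score, 4L)
  expect_equal(sum(vapply(acts, `[[`, 0L, "score")), 17L)
  # round-trip through GeoJSON
  path <- tempfile(fileext = ".geojson")
  write_activities_geojson(acts, path)
  back <- read_activities_geojson(path)
  expect_equal(back$military$polygon, acts$military$polygon,
               ignore_attr = TRUE)
})

test_that("identical config yields identical survey output", {
  r <- small_region()
  s1 <- simulate_survey(small_config(seed = 31), r)
  s2 <- simulate_survey(small_config(seed = 31), r)
  expect_identical(s1$survey$sightings, s2$survey$sightings)
  expect_identical(s1$ctd, s2$ctd)
  expect_identical(s1$indices$monthly, s2$indices$monthly)
})
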