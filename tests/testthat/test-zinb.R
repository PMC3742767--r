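# ZINB likelihood, fitter, diagnostics and selection machinery.

naive_zinb_density <- function(y, mu, pi, alpha) {
  # independent per-observation oracle: direct mixture density
  p0 <- dnbinom(0, size = 1 / alpha, mu = mu)
  ifelse(y == 0, pi + (1 - pi) * p0,
         (1 - pi) * dnbinom(y, size = 1 / alpha, mu = mu))
}

test_that("log-likelihood equals the naive per-observation density oracle", {
  set.seed(2)
  n <- 60
  X <- cbind(1, rnorm(n)); Z <- cbind(1, rnorm(n))
  off <- rnorm(n, 0, 0.3)
  y <- rnbinom(n, size = 1, mu = 2)
  for (k in 1:100) {
    beta <- rnorm(2, 0, 0.7); gamma <- rnorm(2, 0, 0.7)
    alpha <- runif(1, 0.2, 3)
    mu <- exp(as.numeric(X %*% beta) + off)
    pi <- plogis(as.numeric(Z %*% gamma))
    expect_equal(zinb_loglik(y, X, Z, beta, gamma, alpha, off),
                 sum(log(naive_zinb_density(y, mu, pi, alpha))),
                 tolerance = 1e-10)
  }
})

test_that("closed-form single-observation and limit cases hold", {
  X <- matrix(1); Z <- matrix(1)
  # y=0, pi=0.5; with alpha=1, mu=4: NB(0) = (1+mu)^-1 = 0.2 -> density 0.6
  expect_equal(dnbinom(0L, size = 1, mu = 4), 0.2)
  ll <- zinb_loglik(0L, X, Z, beta = log(4), gamma = 0, alpha = 1)
  expect_equal(ll, log(0.5 + 0.5 * 0.2), tolerance = 1e-12)
  # pi -> 0: ZINB likelihood equals plain NB
  y <- c(0L, 3L, 1L)
  X3 <- matrix(1, 3); Z3 <- matrix(1, 3)
  ll_zinb <- zinb_loglik(y, X3, Z3, beta = 0.5, gamma = -40, alpha = 0.7)
  ll_nb <- sum(dnbinom(y, size = 1 / 0.7, mu = exp(0.5), log = TRUE))
  expect_equal(ll_zinb, ll_nb, tolerance = 1e-10)
  # alpha <= 0 rejected
  expect_identical(zinb_loglik(y, X3, Z3, 0.5, 0, -1), -Inf)
})

test_that("analytic gradient matches finite differences", {
  set.seed(5)
  n <- 80
  X <- cbind(1, rnorm(n), rnorm(n)); Z <- cbind(1, rnorm(n))
  off <- rnorm(n, 0, 0.2)
  y <- rnbinom(n, size = 2, mu = 1.5)
  th <- c(0.4, -0.3, 0.2, -0.6, 0.5, log(0.9))
  g <- pelagicplan:::zinb_grad(y, X, Z, th[1:3], th[4:5], th[6], off)
  fn <- function(t) zinb_loglik(y, X, Z, t[1:3], t[4:5], exp(t[6]), off)
  gn <- vapply(seq_along(th), function(i) {
    e <- rep(0, length(th)); e[i] <- 1e-6
    (fn(th + e) - fn(th - e)) / 2e-6
  }, 0)
  expect_equal(g, gn, tolerance = 1e-5)
})

test_that("fitter recovers known parameters and respects the offset contract", {
  bins <- synth_bins(2500, seed = 13)
  truth <- list(count = c(`(Intercept)` = 0.5, sst = 0.5, dist_200 = -0.4),
                infl = c(`(Intercept)` = -0.3, cloud = -0.4), alpha = 1.2)
  bins$SP <- generate_counts_zinb(list(SP = truth), bins, seed = 29)[, "SP"]
  spec <- model_spec("SP", data.frame(var = c("sst", "dist_200"),
                                      form = "linear"),
                     infl = "cloud", controls = character())
  fit <- fit_habitat_model(spec, bins)
  expect_true(fit$converged)
  # per-SD truth maps to per-unit design scale via the reference SDs
  expect_equal(unname(fit$beta["sst"]), 0.5 / 1.62, tolerance = 0.15)
  expect_equal(unname(fit$beta["dist_200"]), -0.4 / 9315, tolerance = 0.35)
  expect_equal(unname(fit$gamma["cloud"]), -0.4 / 3.37, tolerance = 0.5)
  expect_equal(fit$alpha, 1.2, tolerance = 0.35)

  # offset contract: doubling every area doubles predictions at fixed coefs
  p1 <- predict(fit, bins)
  bins2 <- bins; bins2$area_km2 <- 2 * bins2$area_km2
  expect_equal(predict(fit, bins2), 2 * p1, tolerance = 1e-12)
})

test_that("perturbed restarts do not beat the reported optimum", {
  bins <- synth_bins(800, seed = 71)
  truth <- list(count = c(`(Intercept)` = 0.8, sst = 0.4),
                infl = c(`(Intercept)` = -0.5, cloud = -0.3), alpha = 1)
  bins$SP <- generate_counts_zinb(list(SP = truth), bins, seed = 73)[, "SP"]
  spec <- model_spec("SP", data.frame(var = "sst", form = "linear"),
                     infl = "cloud", controls = character())
  fit <- fit_habitat_model(spec, bins)
  th_hat <- c(fit$beta, fit$gamma, log(fit$alpha))
  set.seed(79)
  beats <- 0L
  for (k in 1:12) {
    start <- th_hat + rnorm(length(th_hat), sd = 0.5)
    f2 <- tryCatch(fit_habitat_model(spec, bins, restarts = 0L, start = start),
                   error = function(e) NULL)
    if (!is.null(f2) && f2$loglik > fit$loglik + 1e-4) beats <- beats + 1L
  }
  expect_lte(beats, 0L)
})

test_that("fit on uninflated data pushes the inflation intercept strongly negative", {
  bins <- synth_bins(2000, seed = 17)
  truth <- list(count = c(`(Intercept)` = 0.8, sst = 0.3), infl = NULL,
                alpha = 1.0)
  bins$SP <- generate_counts_zinb(list(SP = truth), bins, seed = 31)[, "SP"]
  spec <- model_spec("SP", data.frame(var = "sst", form = "linear"),
                     infl = character(), controls = character())
  fit <- fit_habitat_model(spec, bins)
  expect_lt(unname(fit$gamma["(Intercept)"]), -1.5)
  expect_equal(fit$alpha, 1.0, tolerance = 0.4)
})

test_that("dispersion LR test is boundary-corrected and detects overdispersion", {
  bins <- synth_bins(2000, seed = 19)
  spec <- model_spec("SP", data.frame(var = "sst", form = "linear"),
                     controls = character(), family = "nb")
  # strongly overdispersed data: decisive rejection
  truth <- list(count = c(`(Intercept)` = 0.8, sst = 0.3), infl = NULL, alpha = 1)
  bins$SP <- generate_counts_zinb(list(SP = truth), bins, seed = 41)[, "SP"]
  nb <- fit_habitat_model(spec, bins, family = "nb")
  po <- fit_habitat_model(spec, bins, family = "poisson")
  tst <- lr_test_alpha(nb, po)
  expect_gte(tst$statistic, 0)
  expect_lt(tst$p, 1e-6)
  expect_equal(tst$preferred, "negbin")
  # identical log-likelihoods -> statistic 0, p = 0.5 under the mixture
  expect_equal(lr_test_alpha(po, po)$p, 0.5)
  # mismatched data errors
  bins2 <- bins[1:500, ]
  po2 <- fit_habitat_model(spec, bins2, family = "poisson")
  expect_error(lr_test_alpha(nb, po2), "identical")
})

test_that("dispersion LR test holds its size near the boundary null", {
  # Poisson-generated data; half-chi-square(1) reference
  spec <- model_spec("SP", data.frame(var = "sst", form = "linear"),
                     controls = character(), family = "nb")
  set.seed(23)
  rej <- vapply(1:60, function(r) {
    bins <- synth_bins(500, seed = 400 + r)
    bins$SP <- rpois(500, exp(0.3 + 0.2 * scale(bins$sst) + log(bins$area_km2)))
    nb <- tryCatch(fit_habitat_model(spec, bins, family = "nb"),
                   error = function(e) NULL)
    if (is.null(nb)) return(NA)
    po <- fit_habitat_model(spec, bins, family = "poisson")
    lr_test_alpha(nb, po)$p < 0.05
  }, NA)
  # 60 reps: permissive binomial band around 5%
  expect_lt(mean(rej, na.rm = TRUE), 0.18)
})

test_that("Vuong test is directional, degenerate-safe, and prefers ZINB under real inflation", {
  bins <- synth_bins(1500, seed = 29)
  truth <- list(count = c(`(Intercept)` = 0.8, sst = 0.4),
                infl = c(`(Intercept)` = -0.4, cloud = -0.4), alpha = 1)
  bins$SP <- generate_counts_zinb(list(SP = truth), bins, seed = 43)[, "SP"]
  spec <- model_spec("SP", data.frame(var = "sst", form = "linear"),
                     infl = "cloud", controls = character())
  zf <- fit_habitat_model(spec, bins)
  nf <- fit_habitat_model(spec, bins, family = "nb")
  v <- vuong_test(zf, nf)
  expect_gt(v$statistic, 0)
  expect_lt(v$p, 0.05)
  expect_equal(v$preferred, "zinb")
  # identical fits: degenerate, statistic 0, p = 0.5
  v0 <- vuong_test(nf, nf)
  expect_true(v0$degenerate)
  expect_equal(v0$statistic, 0)
  expect_equal(v0$p, 0.5)
})

test_that("VIF screen matches closed forms", {
  set.seed(31)
  n <- 5000
  a <- rnorm(n); b <- rnorm(n); c <- rnorm(n)
  v <- vif_screen(data.frame(a = a, b = b, c = c))
  expect_true(all(abs(v$vif - 1) < 0.05))
  expect_true(all(v$pass))
  # duplicated covariate: infinite VIF, fail
  v2 <- vif_screen(data.frame(a = a, a2 = a, b = b))
  expect_true(is.infinite(v2$vif[1]) && is.infinite(v2$vif[2]))
  expect_false(v2$pass[1])
  # correlation 0.95 pair: VIF ~ 1/(1-0.95^2) ~ 10.26 > 10
  x <- rnorm(n); y <- 0.95 * x + sqrt(1 - 0.95^2) * rnorm(n)
  v3 <- vif_screen(data.frame(x = x, y = y, z = rnorm(n)))
  expect_equal(v3$vif[1], 1 / (1 - 0.95^2), tolerance = 0.08 * 10.26)
  expect_false(v3$pass[1])
  expect_error(vif_screen(data.frame(a = a, b = b)), ">= 3")
})

test_that("backward stepwise keeps real effects, drops noise, and respects controls", {
  bins <- synth_bins(2000, seed = 37)
  truth <- list(count = c(`(Intercept)` = 0.5, dist_sefi = -0.8), infl = NULL,
                alpha = 0.8)
  bins$SP <- generate_counts_zinb(list(SP = truth), bins, seed = 47)[, "SP"]
  full <- model_spec("SP",
                     data.frame(var = c("dist_sefi", "sst", "sss", "dist_200"),
                                form = c("quadratic", "linear", "linear", "linear")),
                     controls = c("month", "year"), family = "nb")
  red <- backward_stepwise(full, bins)
  expect_true("dist_sefi" %in% red$spec$count$var)
  expect_identical(red$spec$controls, c("month", "year"))
  # all remaining non-control terms significant
  fit <- fit_habitat_model(red$spec, bins, family = "nb")
  sm <- fit_summary(fit)
  for (d in pelagicplan:::droppable_terms(red$spec)) {
    expect_lte(sm$p[sm$term == d$col], 0.05)
  }
  # single significant covariate: identity
  one <- model_spec("SP", data.frame(var = "dist_sefi", form = "linear"),
                    controls = character(), family = "nb")
  expect_equal(backward_stepwise(one, bins)$spec$count, one$count)
})

test_that("detection-term selection retains the active inflation covariate", {
  bins <- synth_bins(2500, seed = 41)
  truth <- list(count = c(`(Intercept)` = 0.6, sst = 0.4),
                infl = c(`(Intercept)` = -0.2, cloud = -0.6), alpha = 1)
  bins$SP <- generate_counts_zinb(list(SP = truth), bins, seed = 53)[, "SP"]
  spec <- model_spec("SP", data.frame(var = "sst", form = "linear"),
                     infl = c("cloud", "seastate", "visibility"),
                     controls = character())
  red <- select_detection_terms(spec, bins)
  expect_true("cloud" %in% red$infl)
  expect_lt(length(red$infl), 3L)
})

test_that("interaction selection finds a year-varying SST slope and skips when absent", {
  set.seed(43)
  bins <- synth_bins(2400, seed = 43)
  bins$year <- rep(2004:2007, each = 600)
  z <- (bins$sst - 12.6) / 1.62
  slope <- c(`2004` = -0.3, `2005` = 0.5, `2006` = -0.1, `2007` = 0.4)
  mu <- exp(0.6 + slope[as.character(bins$year)] * z + log(bins$area_km2))
  bins$SP <- rnbinom(nrow(bins), size = 1, mu = mu)
  spec <- model_spec("SP", data.frame(var = "sst", form = "linear"),
                     infl = character(), controls = "year")
  sel <- select_interaction(spec, bins)
  expect_identical(sel$spec$interaction, "sst")
  # no oceanographic covariate in the spec: unchanged
  spec2 <- model_spec("SP", data.frame(var = "dist_200", form = "linear"),
                      infl = character(), controls = "year")
  sel2 <- select_interaction(spec2, bins)
  expect_null(sel2$spec$interaction)
})

test_that("cross-validation predicts each observation exactly once and flags real signal", {
  bins <- synth_bins(400, seed = 47)
  truth <- list(count = c(`(Intercept)` = 0.6, sst = 0.8), infl = NULL,
                alpha = 0.5)
  bins$SP <- generate_counts_zinb(list(SP = truth), bins, seed = 59)[, "SP"]
  spec <- model_spec("SP", data.frame(var = "sst", form = "linear"),
                     controls = character(), family = "nb")
  cv <- cross_validate(spec, bins, folds = 5, seed = 7)
  expect_equal(sum(is.na(cv$predicted)), 0L)
  expect_lt(cv$p, 0.05)
  # leave-one-out on tiny data still partitions correctly
  tiny <- bins[1:40, ]
  cv2 <- cross_validate(spec, tiny, folds = 40, seed = 7)
  expect_true(all(!is.na(cv2$predicted) | seq_len(40) %in% cv2$folds_failed))
})

test_that("ZINB fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("glmmTMB")
  bins <- synth_bins(1500, seed = 53)
  truth <- list(count = c(`(Intercept)` = 0.5, sst = 0.4),
                infl = c(`(Intercept)` = -0.5, cloud = -0.3), alpha = 1.3)
  bins$SP <- generate_counts_zinb(list(SP = truth), bins, seed = 61)[, "SP"]
  spec <- model_spec("SP", data.frame(var = "sst", form = "linear"),
                     infl = "cloud", controls = character())
  fit <- fit_habitat_model(spec, bins)
  bins$sst_c <- bins$sst - mean(bins$sst)
  bins$cloud_c <- bins$cloud - mean(bins$cloud)
  tmb <- glmmTMB::glmmTMB(SP ~ sst_c + offset(log(area_km2)),
                          ziformula = ~cloud_c, family = glmmTMB::nbinom2,
                          data = bins)
  expect_equal(fit$loglik, as.numeric(logLik(tmb)), tolerance = 1e-4)
  expect_equal(unname(fit$beta["sst"]),
               unname(glmmTMB::fixef(tmb)$cond["sst_c"]), tolerance = 1e-3)
  expect_equal(unname(fit$gamma["cloud"]),
               unname(glmmTMB::fixef(tmb)$zi["cloud_c"]), tolerance = 1e-2)
  expect_equal(fit$alpha, 1 / glmmTMB::sigma(tmb), tolerance = 1e-3)
})
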