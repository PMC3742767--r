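# Variogram fitting, detrending and ordinary-kriging correctness.

grid_pts <- function(nx, ny, step = 1000) {
  as.matrix(expand.grid(x = seq(0, by = step, length.out = nx),
                        y = seq(0, by = step, length.out = ny)))
}

# draw from a known variogram model by Cholesky of the implied covariance
sim_gaussian_field <- function(pts, model, seed = 1) {
  set.seed(seed)
  h <- as.matrix(dist(pts))
  sill <- model$nugget + model$psill
  C <- sill - variogram_gamma(h, model$family, model$nugget, model$psill,
                              model$range)
  diag(C) <- sill
  L <- chol(C + diag(1e-8, nrow(C)))
  as.numeric(t(L) %*% rnorm(nrow(pts)))
}

test_that("nugget-free kriging interpolates exactly with unit-sum weights", {
  pts <- grid_pts(6, 6)
  model <- variogram_model("exponential", nugget = 0, psill = 2, range = 4000)
  vals <- sim_gaussian_field(pts, model, seed = 3)
  surf <- krige(pts, vals, model, pts)
  expect_equal(surf$pred, vals, tolerance = 1e-8)
  expect_true(all(surf$variance < 1e-6))
  w <- kriging_weights(pts, vals, model, rbind(c(1500, 2500), c(-3000, 8000)))
  for (wi in w) expect_equal(sum(wi), 1, tolerance = 1e-10)
})

test_that("kriging far beyond the range reverts toward the neighborhood mean", {
  pts <- grid_pts(5, 5, step = 100)
  set.seed(4)
  vals <- rnorm(25, 10, 1)
  # pure-nugget model: equal weights, the sample mean exactly
  pure <- variogram_model("spherical", nugget = 1, psill = 0, range = 300)
  far <- krige(pts, vals, pure, matrix(c(1e6, 1e6), 1), neighbors = 25)
  expect_equal(far$pred, mean(vals), tolerance = 1e-8)
  expect_true(far$extrapolated)
  # with structure the far-field prediction still approaches the mean
  model <- variogram_model("spherical", nugget = 0.1, psill = 1, range = 300)
  far2 <- krige(pts, vals, model, matrix(c(1e6, 1e6), 1), neighbors = 25)
  expect_lt(abs(far2$pred - mean(vals)), sd(vals) / 2)
})

test_that("5-point kriging system matches a hand-assembled linear solve", {
  pts <- rbind(c(0, 0), c(1000, 0), c(0, 1000), c(1200, 900), c(500, 500))
  vals <- c(1.2, 0.7, 1.9, 0.4, 1.1)
  model <- variogram_model("exponential", nugget = 0.05, psill = 1.5,
                           range = 800)
  target <- c(700, 300)
  gf <- function(h) ifelse(h == 0, 0, 0.05 + 1.5 * (1 - exp(-h / 800)))
  G <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5)
    G[i, j] <- gf(sqrt(sum((pts[i, ] - pts[j, ])^2)))
  A <- rbind(cbind(G, 1), c(rep(1, 5), 0))
  b <- c(gf(sqrt(colSums((t(pts) - target)^2))), 1)
  sol <- solve(A, b)
  expected <- sum(sol[1:5] * vals)
  surf <- krige(pts, vals, model, matrix(target, 1), neighbors = 5)
  expect_equal(surf$pred, expected, tolerance = 1e-8)
})

test_that("kriging variance is zero at data and grows with distance to data", {
  shifted <- grid_pts(4, 2, 500); shifted[, 2] <- shifted[, 2] + 6000
  pts <- rbind(grid_pts(4, 2, 500), shifted)
  model <- variogram_model("exponential", nugget = 0, psill = 1, range = 2000)
  vals <- sim_gaussian_field(pts, model, seed = 9)
  # transect-gap layout: nodes marching into the gap between two rows
  nodes <- cbind(500, seq(500, 3250, by = 250))
  surf <- krige(pts, vals, model, nodes)
  expect_equal(surf$variance[1], 0, tolerance = 1e-8)
  expect_true(all(diff(surf$variance) > -1e-9))
})

test_that("variogram fitting recovers range and separates noise from structure", {
  pts <- grid_pts(14, 14, 700)
  truth <- variogram_model("exponential", nugget = 0, psill = 1.5,
                           range = 3000)
  vals <- sim_gaussian_field(pts, truth, seed = 11)
  fit <- fit_variogram(pts, vals, families = "exponential")
  expect_lt(abs(fit$range - 3000) / 3000, 0.6)
  expect_lt(fit$nugget, 0.5 * (fit$nugget + fit$psill))
  # pure white noise: nugget should dominate the sill
  set.seed(13)
  noise <- rnorm(nrow(pts), 0, 1)
  fitn <- fit_variogram(pts, noise)
  expect_gt(fitn$nugget / (fitn$nugget + fitn$psill), 0.6)
  expect_equal(fitn$nugget + fitn$psill, var(noise), tolerance = 0.5)
  # insufficient points
  expect_error(fit_variogram(pts[1:2, ], vals[1:2]), "at least 3")
  # identical values: degenerate with warning
  expect_warning(fit_variogram(pts[1:30, ], rep(1, 30)), "identical")
})

test_that("detrending removes an exact plane and keeps its false-trigger rate low", {
  pts <- grid_pts(8, 8, 900)
  plane <- 2 + 3e-4 * pts[, 1] - 1e-4 * pts[, 2]
  dt <- detrend(pts, plane)
  expect_true(dt$triggered)
  expect_true(all(abs(dt$residuals) < 1e-8))
  expect_equal(dt$coefficients, c(2, 3e-4, -1e-4), tolerance = 1e-6)
  expect_lt(abs(mean(dt$residuals)), 1e-10)
  # plane + noise: coefficients recovered within 2 SE of the OLS oracle
  set.seed(17)
  noisy <- plane + rnorm(64, 0, 0.3)
  dt2 <- detrend(pts, noisy)
  ols <- summary(lm(noisy ~ pts[, 1] + pts[, 2]))$coefficients
  expect_lt(abs(dt2$coefficients[2] - 3e-4), 2 * ols[2, 2])
  expect_lt(abs(dt2$coefficients[3] + 1e-4), 2 * ols[3, 2])
  # trend-free data triggers rarely (null simulation)
  trig <- vapply(1:40, function(r) {
    detrend(pts, rnorm(64), level = 0.05)$triggered
  }, NA)
  expect_lt(mean(trig), 0.2)
  # collinear layout skipped with warning
  line_pts <- cbind(seq(0, 9000, length.out = 12), 0)
  expect_warning(detrend(line_pts, rnorm(12)), "collinear")
})

test_that("duplicate data locations are averaged rather than breaking the solve", {
  pts <- rbind(grid_pts(4, 4), c(0, 0))
  vals <- c(sim_gaussian_field(grid_pts(4, 4),
                               variogram_model("exponential", 0.1, 1, 2000), 5), 4)
  model <- variogram_model("exponential", nugget = 0.1, psill = 1, range = 2000)
  surf <- krige(pts, vals, model, matrix(c(500, 500), 1))
  expect_true(is.finite(surf$pred))
})

test_that("surface suite produces 3 surfaces per cruise and near-zero RMSE on smooth fields", {
  tab <- small_table()$table
  grid <- grid_pts(8, 8, 2500)
  suite <- surface_suite(tab, grid, min_points = 12)
  n_cruises <- length(unique(tab$cruise_id))
  expect_equal(sum(vapply(suite$surfaces, length, 0L)), 3L * n_cruises)
  expect_equal(nrow(suite$rmse), 3L * n_cruises)
  expect_equal(suite$rmse_summary$n_surfaces, rep(n_cruises, 3))
  # single cruise: 3 surfaces
  one <- surface_suite(tab[tab$cruise_id == "C01", ], grid, min_points = 12)
  expect_equal(length(one$surfaces$C01), 3L)
  # smooth noiseless field: tiny RMSE relative to the field's SD
  sub <- tab[tab$cruise_id == "C01", ]
  m <- fit_variogram(cbind(sub$x, sub$y), sub$sst)
  expect_lt(attr(m, "loo_rmse"), sd(sub$sst))
  # a cruise below the minimum point count is skipped and reported
  few <- tab[tab$cruise_id == "C01", ][1:10, ]
  s2 <- surface_suite(few, grid)
  expect_equal(nrow(s2$skipped), 3L)
})

test_that("kriging RMSE improves as sampling density doubles", {
  truth <- variogram_model("exponential", nugget = 0.05, psill = 1,
                           range = 3000)
  dense <- grid_pts(16, 16, 600)
  vals <- sim_gaussian_field(dense, truth, seed = 23)
  idx_sparse <- seq(1, 256, by = 4)
  idx_mid <- seq(1, 256, by = 2)
  rmse_of <- function(idx) {
    m <- fit_variogram(dense[idx, ], vals[idx], families = "exponential")
    attr(m, "loo_rmse")
  }
  r_sparse <- rmse_of(idx_sparse)
  r_dense <- rmse_of(seq_len(256))
  expect_lt(r_dense, r_sparse * 1.1)
})
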