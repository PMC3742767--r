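# Per-cruise ordinary kriging of surface-water variables. Spatial structure
# is summarized by an isotropic empirical semivariogram (binned pairwise
# half-squared differences), candidate variogram families are fitted by
# weighted least squares, and the family is chosen by leave-one-out
# cross-validation MSE of kriging predictions (the stated optimization
# objective). A first-order trend surface is removed first when the trend
# diagnostic triggers.

#' Empirical semivariogram
#'
#' Binned half mean squared differences of values over pairwise separation
#' distances: 12 lags to half the maximum pairwise distance by default.
#'
#' @param pts n x 2 matrix of locations (meters).
#' @param values numeric vector.
#' @param n_lags number of lag bins.
#' @param max_dist maximum lag distance (default half the max pairwise
#'   distance).
#' @return data.frame `dist` (mean pair distance per bin), `gamma`
#'   (semivariance), `n_pairs`.
#' @export
empirical_variogram <- function(pts, values, n_lags = 12, max_dist = NULL) {
  pts <- coerce_xy(pts)
  n <- nrow(pts)
  stopifnot(n >= 2L)
  d <- as.numeric(stats::dist(pts))
  g <- 0.5 * as.numeric(stats::dist(values))^2
  if (is.null(max_dist)) max_dist <- max(d) / 2
  keep <- d <= max_dist & d > 0
  d <- d[keep]; g <- g[keep]
  brk <- seq(0, max_dist, length.out = n_lags + 1L)
  bin <- cut(d, brk, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(
    dist = tapply(d, bin, mean),
    gamma = tapply(g, bin, mean),
    n_pairs = as.integer(table(factor(bin, levels = seq_len(n_lags)))[
      names(tapply(d, bin, mean))]))
  rownames(out) <- NULL
  out[stats::complete.cases(out), ]
}

# semivariance gamma(h) for the three supported isotropic families
variogram_gamma <- function(h, family, nugget, psill, range) {
  s <- switch(family,
    exponential = 1 - exp(-h / range),
    gaussian = 1 - exp(-(h / range)^2),
    spherical = ifelse(h >= range, 1,
                       1.5 * h / range - 0.5 * (h / range)^3),
    stop("unknown variogram family: ", family))
  out <- nugget + psill * s
  out[h == 0] <- 0
  out
}

#' Construct a variogram model
#'
#' @param family `"exponential"`, `"spherical"` or `"gaussian"`.
#' @param nugget non-negative nugget variance.
#' @param psill non-negative partial sill.
#' @param range range parameter (> 0).
#' @param trend_order 0 (none) or 1 (first-order trend surface removed before
#'   kriging).
#' @param cruise_id,variable optional labels.
#' @return object of class `variogram_model`.
#' @export
variogram_model <- function(family, nugget, psill, range, trend_order = 0,
                            cruise_id = NA, variable = NA) {
  stopifnot(family %in% c("exponential", "spherical", "gaussian"),
            nugget >= 0, psill >= 0, range > 0, trend_order %in% c(0, 1))
  if (nugget + psill <= 0) stop("nugget + partial sill must be > 0")
  structure(list(family = family, nugget = nugget, psill = psill,
                 range = range, trend_order = trend_order,
                 cruise_id = cruise_id, variable = variable),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram: %s nugget=%.4g psill=%.4g range=%.0f trend=%d\n",
              x$family, x$nugget, x$psill, x$range, x$trend_order))
  invisible(x)
}

# WLS fit of one family to the empirical variogram (Cressie-style weights
# n_pairs / gamma_model^2), on log-parameter scale. The range is bounded
# below by the first lag distance: sub-lag ranges are indistinguishable from
# nugget and would leave the split unidentified.
fit_family_wls <- function(ev, family, var0, dmax) {
  rg_min <- min(ev$dist)
  obj <- function(par) {
    nug <- exp(par[1]); ps <- exp(par[2]); rg <- rg_min + exp(par[3])
    gm <- variogram_gamma(ev$dist, family, nug, ps, rg)
    w <- ev$n_pairs / pmax(gm, 1e-10)^2
    sum(w * (ev$gamma - gm)^2)
  }
  starts <- list(c(log(var0 * 0.1 + 1e-8), log(var0 * 0.9 + 1e-8), log(dmax / 3)),
                 c(log(var0 * 0.5 + 1e-8), log(var0 * 0.5 + 1e-8), log(dmax / 6)))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(stats::optim(s, obj, method = "Nelder-Mead",
                               control = list(maxit = 500)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  list(nugget = exp(best$par[1]), psill = exp(best$par[2]),
       range = rg_min + exp(best$par[3]))
}

#' Fit a variogram model with cross-validated family selection
#'
#' Fits each candidate family to the empirical semivariogram by weighted
#' least squares, then selects the family whose ordinary-kriging leave-one-out
#' predictions minimize mean squared error. Identical values give a
#' degenerate model (sill ~ 0) with a warning.
#'
#' @param pts n x 2 matrix of locations (n >= 20 for a stable fit; >= 3
#'   distinct locations required).
#' @param values numeric vector.
#' @param families candidate families to try.
#' @param n_lags lag bins for the empirical variogram.
#' @param neighbors kriging search-neighborhood size used during LOO scoring.
#' @return a `variogram_model` with attributes `loo_mse` and `loo_rmse`.
#' @export
fit_variogram <- function(pts, values,
                          families = c("exponential", "spherical", "gaussian"),
                          n_lags = 12, neighbors = 16) {
  pts <- coerce_xy(pts)
  if (nrow(pts) < 3L || nrow(unique(pts)) < 3L)
    stop("need at least 3 distinct locations to fit a variogram")
  v0 <- stats::var(values)
  if (v0 < 1e-14) {
    warning("all values identical: degenerate variogram (zero sill)")
    m <- variogram_model(families[1], 0, 1e-12, max(stats::dist(pts)) / 2)
    attr(m, "loo_mse") <- 0; attr(m, "loo_rmse") <- 0
    return(m)
  }
  ev <- empirical_variogram(pts, values, n_lags)
  dmax <- max(ev$dist)
  best <- NULL
  for (fam in families) {
    par <- fit_family_wls(ev, fam, v0, dmax)
    m <- variogram_model(fam, par$nugget, par$psill, par$range)
    mse <- loo_mse(pts, values, m, neighbors)
    if (is.null(best) || mse < attr(best, "loo_mse")) {
      attr(m, "loo_mse") <- mse
      best <- m
    }
  }
  # parsimony: on spatially unstructured data the nugget/short-range split is
  # unidentified; prefer the pure-nugget model when it predicts as well
  m0 <- variogram_model(best$family, v0, 0, dmax / 2)
  mse0 <- loo_mse(pts, values, m0, neighbors)
  if (mse0 <= attr(best, "loo_mse") * 1.01) {
    attr(m0, "loo_mse") <- mse0
    best <- m0
  }
  attr(best, "loo_rmse") <- sqrt(attr(best, "loo_mse"))
  best
}

# leave-one-out kriging MSE under a given variogram model
loo_mse <- function(pts, values, model, neighbors = 16) {
  n <- nrow(pts)
  err <- vapply(seq_len(n), function(i) {
    p <- krige_points(pts[-i, , drop = FALSE], values[-i], model,
                      pts[i, , drop = FALSE], neighbors)$pred
    p - values[i]
  }, 0)
  mean(err^2)
}

#' First-order trend surface detection and removal
#'
#' Fits the least-squares plane `v ~ x + y`. The trend is deemed present
#' (trigger) when the plane's F test is significant at `level` or the
#' empirical semivariogram keeps growing at the largest lags (slope of the
#' upper half of lags significantly positive and the final semivariance above
#' the sample variance). Collinear layouts skip detrending with a warning.
#'
#' @param pts n x 2 matrix (n >= 10).
#' @param values numeric vector.
#' @param level significance level for the trigger.
#' @return list with `triggered`, `coefficients` (intercept, b_x, b_y),
#'   `residuals`, `fitted`, `p_plane`.
#' @export
detrend <- function(pts, values, level = 0.05) {
  pts <- coerce_xy(pts)
  stopifnot(nrow(pts) >= 10L)
  df <- data.frame(v = values, x = pts[, 1], y = pts[, 2])
  if (qr(cbind(1, pts))$rank < 3L) {
    warning("collinear point layout: trend surface skipped")
    return(list(triggered = FALSE, coefficients = c(mean(values), 0, 0),
                residuals = values - mean(values),
                fitted = rep(mean(values), length(values)), p_plane = NA))
  }
  fit <- stats::lm(v ~ x + y, data = df)
  fs <- summary(fit)$fstatistic
  p_plane <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  unbounded <- FALSE
  if (nrow(pts) >= 20L) {
    ev <- empirical_variogram(pts, values)
    if (nrow(ev) >= 6L) {
      upper <- ev[ev$dist > max(ev$dist) / 2, ]
      if (nrow(upper) >= 3L) {
        sl <- summary(stats::lm(gamma ~ dist, data = upper))$coefficients
        unbounded <- nrow(sl) >= 2 && sl[2, 1] > 0 && sl[2, 4] < level &&
          ev$gamma[nrow(ev)] > stats::var(values)
      }
    }
  }
  triggered <- (is.finite(p_plane) && p_plane < level) || unbounded
  list(triggered = triggered, coefficients = unname(stats::coef(fit)),
       residuals = stats::residuals(fit), fitted = stats::fitted(fit),
       p_plane = unname(p_plane))
}

# ordinary kriging of arbitrary prediction points; duplicates in the data are
# averaged first. Nodes sharing a search neighborhood are solved together
# (one factorization, many right-hand sides). Returns pred, variance,
# weights (optionally) per node.
krige_points <- function(pts, values, model, newpts, neighbors = 16,
                         keep_weights = FALSE) {
  pts <- coerce_xy(pts); newpts <- coerce_xy(newpts)
  key <- paste(pts[, 1], pts[, 2])
  if (anyDuplicated(key)) {
    agg <- tapply(values, key, mean)
    first <- !duplicated(key)
    pts <- pts[first, , drop = FALSE]
    values <- as.numeric(agg[paste(pts[, 1], pts[, 2])])
  }
  n <- nrow(pts)
  m <- nrow(newpts)
  k <- min(neighbors, n)
  gfun <- function(h) variogram_gamma(h, model$family, model$nugget,
                                      model$psill, model$range)
  # m x n distances and per-node nearest-k neighbor sets
  D <- outer(newpts[, 1], pts[, 1], "-")^2 + outer(newpts[, 2], pts[, 2], "-")^2
  D <- sqrt(D)
  nbr <- t(apply(D, 1, function(d) sort(order(d)[seq_len(k)])))
  if (k == 1L) nbr <- matrix(nbr, ncol = 1L)
  grp_key <- apply(nbr, 1, paste, collapse = ",")
  pred <- var_out <- numeric(m)
  wts <- if (keep_weights) vector("list", m) else NULL
  for (g in split(seq_len(m), grp_key)) {
    idx <- nbr[g[1], ]
    P <- pts[idx, , drop = FALSE]
    G <- gfun(as.matrix(stats::dist(P)))
    A <- rbind(cbind(G, 1), c(rep(1, k), 0))
    B <- rbind(gfun(t(D[g, idx, drop = FALSE])), 1)
    sol <- tryCatch(solve(A, B), error = function(e)
      solve(A + diag(1e-10, k + 1), B))
    W <- sol[seq_len(k), , drop = FALSE]
    pred[g] <- as.numeric(crossprod(W, values[idx]))
    var_out[g] <- pmax(0, colSums(W * B[seq_len(k), , drop = FALSE]) +
                         sol[k + 1L, ])
    if (keep_weights) for (j in seq_along(g)) wts[[g[j]]] <- W[, j]
  }
  list(pred = pred, variance = var_out, weights = wts)
}

#' Ordinary kriging onto a grid
#'
#' Solves the constrained ordinary-kriging system (weights sum to 1) in a
#' nearest-neighbor search window at every node. With a zero nugget the
#' predictor interpolates the data exactly; far beyond the variogram range
#' predictions revert toward the local mean. If the model was built on
#' detrended residuals (`trend_order = 1`), supply the `trend` coefficients
#' so the plane is added back.
#'
#' @param pts n x 2 data locations.
#' @param values data values (residuals if `trend` is supplied).
#' @param model a [variogram_model()].
#' @param grid m x 2 matrix of prediction nodes.
#' @param neighbors search-neighborhood size (default 16 nearest points).
#' @param trend optional length-3 plane coefficients (intercept, b_x, b_y)
#'   added back to predictions.
#' @param extrap_km distance beyond which nodes are flagged as extrapolated
#'   (default 25 km beyond survey coverage).
#' @return object of class `kriged_surface`: `grid`, `pred`, `variance`,
#'   `extrapolated` flag per node, and the `model`.
#' @export
krige <- function(pts, values, model, grid, neighbors = 16, trend = NULL,
                  extrap_km = 25) {
  grid <- coerce_xy(grid)
  stopifnot(all(is.finite(grid)))
  kp <- krige_points(pts, values, model, grid, neighbors)
  pred <- kp$pred
  if (!is.null(trend))
    pred <- pred + trend[1] + trend[2] * grid[, 1] + trend[3] * grid[, 2]
  pts <- coerce_xy(pts)
  nearest <- vapply(seq_len(nrow(grid)), function(j) {
    min(sqrt((pts[, 1] - grid[j, 1])^2 + (pts[, 2] - grid[j, 2])^2))
  }, 0)
  structure(list(grid = grid, pred = pred, variance = kp$variance,
                 extrapolated = nearest > extrap_km * 1000, model = model),
            class = "kriged_surface")
}

#' Kriging weights at prediction nodes
#'
#' Exposes the ordinary-kriging weight vectors (for checking the sum-to-one
#' constraint and exactness).
#'
#' @inheritParams krige
#' @return list of numeric weight vectors, one per node.
#' @export
kriging_weights <- function(pts, values, model, grid, neighbors = 16) {
  krige_points(pts, values, model, coerce_xy(grid), neighbors,
               keep_weights = TRUE)$weights
}

#' Krige every (cruise, variable) surface of a model table
#'
#' For each cruise and each of SST/SSS/SSF: fits a variogram (with
#' cross-validated family selection), records the leave-one-out RMSE, and
#' interpolates onto the grid. Cruises whose per-variable RMSE exceeds the
#' across-cruise mean + 2 SD are flagged as outliers and re-run with
#' first-order detrending when the trend diagnostic triggers. Cruises with
#' fewer than `min_points` observed bins are skipped and reported.
#'
#' @param table model table from [build_model_table()] (needs `cruise_id`,
#'   `x`, `y` and the variable columns).
#' @param grid m x 2 matrix of prediction nodes.
#' @param variables variables to interpolate.
#' @param min_points minimum bins per surface.
#' @param neighbors kriging neighborhood.
#' @return object of class `surface_suite`: `surfaces` (nested
#'   `[[cruise]][[variable]]` of `kriged_surface`), `rmse` (long data.frame),
#'   `rmse_summary` (per-variable mean/SD), `outliers`, `skipped`.
#' @export
surface_suite <- function(table, grid, variables = c("sst", "sss", "ssf"),
                          min_points = 20, neighbors = 16) {
  cruises <- unique(table$cruise_id)
  surfaces <- list(); rmse_rows <- list(); skipped <- list()
  for (cid in cruises) {
    sub <- table[table$cruise_id == cid, ]
    surfaces[[cid]] <- list()
    for (v in variables) {
      ok <- is.finite(sub[[v]])
      if (sum(ok) < min_points) {
        skipped[[length(skipped) + 1L]] <- data.frame(cruise_id = cid,
                                                      variable = v,
                                                      n = sum(ok))
        next
      }
      pts <- cbind(sub$x[ok], sub$y[ok])
      vals <- sub[[v]][ok]
      model <- fit_variogram(pts, vals, neighbors = neighbors)
      model$cruise_id <- cid; model$variable <- v
      surf <- krige(pts, vals, model, grid, neighbors)
      surf$rmse <- attr(model, "loo_rmse")
      surfaces[[cid]][[v]] <- surf
      rmse_rows[[length(rmse_rows) + 1L]] <-
        data.frame(cruise_id = cid, variable = v, rmse = surf$rmse,
                   detrended = FALSE)
    }
  }
  rmse <- do.call(rbind, rmse_rows)
  if (is.null(rmse))
    rmse <- data.frame(cruise_id = character(), variable = character(),
                       rmse = numeric(), detrended = logical())
  # outlier pass: re-run high-RMSE surfaces with detrending when triggered
  outliers <- list()
  for (v in variables) {
    rv <- rmse[rmse$variable == v, ]
    if (nrow(rv) < 3L) next
    cut <- mean(rv$rmse) + 2 * stats::sd(rv$rmse)
    for (cid in rv$cruise_id[rv$rmse > cut]) {
      sub <- table[table$cruise_id == cid, ]
      ok <- is.finite(sub[[v]])
      pts <- cbind(sub$x[ok], sub$y[ok]); vals <- sub[[v]][ok]
      dt <- detrend(pts, vals)
      outliers[[length(outliers) + 1L]] <-
        data.frame(cruise_id = cid, variable = v,
                   rmse = rv$rmse[rv$cruise_id == cid],
                   detrended = dt$triggered)
      if (!dt$triggered) next
      model <- fit_variogram(pts, dt$residuals, neighbors = neighbors)
      model$cruise_id <- cid; model$variable <- v; model$trend_order <- 1
      surf <- krige(pts, dt$residuals, model, grid, neighbors,
                    trend = dt$coefficients)
      surf$rmse <- attr(model, "loo_rmse")
      surfaces[[cid]][[v]] <- surf
      i <- which(rmse$cruise_id == cid & rmse$variable == v)
      rmse$rmse[i] <- surf$rmse; rmse$detrended[i] <- TRUE
    }
  }
  summ <- do.call(rbind, lapply(variables, function(v) {
    rv <- rmse$rmse[rmse$variable == v]
    data.frame(variable = v, n_surfaces = length(rv),
               rmse_mean = if (length(rv)) mean(rv) else NA_real_,
               rmse_sd = if (length(rv) > 1) stats::sd(rv) else NA_real_)
  }))
  structure(list(surfaces = surfaces, rmse = rmse, rmse_summary = summ,
                 outliers = if (length(outliers)) do.call(rbind, outliers)
                 else data.frame(),
                 skipped = if (length(skipped)) do.call(rbind, skipped)
                 else data.frame()),
            class = "surface_suite")
}

#' @export
print.surface_suite <- function(x, ...) {
  n <- sum(vapply(x$surfaces, length, 0L))
  cat("surface_suite:", n, "kriged surfaces\n")
  print(x$rmse_summary)
  invisible(x)
}
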