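# 1-km2 prediction grid, per-cruise abundance prediction, and standardized
# single-/multi-species habitat-selection maps with percent ranking.

#' Build the prediction-cell grid
#'
#' Regular square cells aligned to the region's minimum corner; every cell
#' whose centroid lies inside the region or within the buffer distance of it
#' is included (centroids exactly on the boundary count as inside). Distance
#' covariates are computed as for survey bins.
#'
#' @param region a [study_region()].
#' @param resolution cell side (meters; default 1 km).
#' @param buffer buffer beyond the region boundary (meters; default 5 km).
#' @return data.frame of cells: `cell_id`, `x`, `y` (centroid), `inside`
#'   (in-region flag), `buffered` (within buffer only), `dist_land`,
#'   `dist_200`, `dist_sefi`, `area_km2` (always `resolution^2 / 1e6`).
#' @export
build_grid <- function(region, resolution = 1000, buffer = 5000) {
  bb <- apply(region$boundary, 2, range)
  xs <- seq(bb[1, 1] - buffer + resolution / 2, bb[2, 1] + buffer,
            by = resolution)
  ys <- seq(bb[1, 2] - buffer + resolution / 2, bb[2, 2] + buffer,
            by = resolution)
  g <- expand.grid(x = xs, y = ys)
  pts <- as.matrix(g)
  d <- dist_to_polygon(pts, region$boundary)
  keep <- d <= buffer
  cells <- g[keep, , drop = FALSE]
  d <- d[keep]
  cells$cell_id <- seq_len(nrow(cells))
  cells$inside <- d == 0
  cells$buffered <- d > 0
  cells <- compute_distances(cells, region)
  cells$area_km2 <- (resolution / 1000)^2
  rownames(cells) <- NULL
  cells[, c("cell_id", "x", "y", "inside", "buffered", "dist_land",
            "dist_200", "dist_sefi", "area_km2")]
}

#' Most frequent value of each detection-bias variable
#'
#' @param table model table.
#' @param vars detection-condition columns.
#' @return named list of modal values (ties broken toward the smaller value).
#' @export
modal_detection_values <- function(table,
                                   vars = c("cloud", "seastate", "swell_m",
                                            "visibility", "time")) {
  out <- lapply(vars, function(v) {
    tab <- table(table[[v]])
    as.numeric(names(tab)[which.max(tab)])
  })
  names(out) <- vars
  out
}

#' Build the per-cruise prediction data for grid cells
#'
#' Samples the kriged SST/SSS/SSF surfaces at cell centroids, attaches the
#' cruise's climate indices, and fills detection-bias variables with their
#' modal observed values. Exposure is one grid cell (1 km2).
#'
#' @param cells grid from [build_grid()].
#' @param suite a `surface_suite`.
#' @param cruise_id cruise to assemble.
#' @param table model table (for indices and modal detection values).
#' @return data.frame of cell-level covariates for that cruise (with
#'   `extrapolated` flag from the kriged surfaces).
#' @export
cell_covariates <- function(cells, suite, cruise_id, table) {
  surfs <- suite$surfaces[[cruise_id]]
  if (is.null(surfs) || length(surfs) == 0L)
    stop("no kriged surfaces for cruise ", cruise_id)
  out <- cells
  extrap <- rep(FALSE, nrow(cells))
  for (v in names(surfs)) {
    out[[v]] <- surfs[[v]]$pred
    extrap <- extrap | surfs[[v]]$extrapolated
  }
  out$extrapolated <- extrap
  sub <- table[table$cruise_id == cruise_id, ]
  for (v in c("npgo", "pdo", "soi", "ui", "year", "month")) {
    out[[v]] <- sub[[v]][1]
  }
  fills <- modal_detection_values(table)
  for (v in names(fills)) out[[v]] <- fills[[v]]
  out$area_km2 <- cells$area_km2
  out
}

#' Predict per-cell expected abundance for one cruise
#'
#' Expectation of the fitted mixture at 1-km2 exposure,
#' `(1 - pi_hat(z)) * exp(x' beta_hat + log 1)`; plain `exp(x' beta_hat)` for
#' a negative-binomial fit. Cells with covariates far outside the training
#' range (3x the observed range width) are still predicted but flagged.
#'
#' @param fit a `habitat_fit`.
#' @param cellcov per-cruise cell covariates from [cell_covariates()].
#' @return data.frame `cell_id`, `pred`, `flag_covariate` (out-of-range
#'   flag), `extrapolated`.
#' @export
predict_abundance <- function(fit, cellcov) {
  if (!fit$converged) stop("refusing to predict from a non-converged fit")
  pred <- predict(fit, cellcov)
  flag <- rep(FALSE, nrow(cellcov))
  for (v in unique(fit$spec$count$var)) {
    r <- fit$ref$ranges[[v]]
    mid <- mean(r); hw <- diff(r) / 2
    flag <- flag | abs(cellcov[[v]] - mid) > 3 * hw
  }
  data.frame(cell_id = cellcov$cell_id, pred = pred, flag_covariate = flag,
             extrapolated = cellcov$extrapolated)
}

#' Standardize per-cruise predictions into habitat-use indices
#'
#' Within each cruise the cell values are divided by the cross-cell mean so
#' each cruise layer has mean exactly 1 (a relative-use index; a z-score
#' alternative is available via `method`). Monthly layers average the cruise
#' layers of a calendar month across years; the across-months-and-years layer
#' is the mean of the monthly layers, re-scaled to mean 1 so every species
#' contributes equally to the composite. All-zero cruise surfaces are dropped
#' with a warning.
#'
#' @param pred_matrix cells x cruises matrix of predicted abundances.
#' @param calendar cruise calendar (with `cruise_id`, `month`); column order
#'   must match `pred_matrix` columns.
#' @param method `"mean"` (divide by cell average, default) or `"zscore"`.
#' @return list with `monthly` (cells x months matrix), `overall` (numeric
#'   per cell, mean 1), `dropped` (cruise ids of all-zero surfaces).
#' @export
standardize_predictions <- function(pred_matrix, calendar,
                                    method = c("mean", "zscore")) {
  method <- match.arg(method)
  stopifnot(ncol(pred_matrix) == nrow(calendar))
  colnames(pred_matrix) <- calendar$cruise_id
  dropped <- character()
  std <- matrix(NA_real_, nrow(pred_matrix), ncol(pred_matrix),
                dimnames = dimnames(pred_matrix))
  for (j in seq_len(ncol(pred_matrix))) {
    v <- pred_matrix[, j]
    m <- mean(v)
    if (!is.finite(m) || m <= 0) {
      warning("all-zero prediction surface for cruise ",
              calendar$cruise_id[j], "; dropped")
      dropped <- c(dropped, calendar$cruise_id[j])
      next
    }
    std[, j] <- if (method == "mean") v / m else (v - m) / stats::sd(v)
  }
  keep <- !calendar$cruise_id %in% dropped
  months <- sort(unique(calendar$month[keep]))
  monthly <- vapply(months, function(mo) {
    cols <- which(keep & calendar$month == mo)
    rowMeans(std[, cols, drop = FALSE])
  }, numeric(nrow(std)))
  colnames(monthly) <- months
  overall <- rowMeans(monthly)
  if (method == "mean") overall <- overall / mean(overall)
  list(monthly = monthly, overall = overall, dropped = dropped)
}

#' Percent rank of values
#'
#' `(rank - 1) / (n - 1)` with average ranks for ties; in [0, 1].
#'
#' @param x numeric vector (length >= 2).
#' @return numeric vector of percent ranks.
#' @export
percent_rank <- function(x) {
  n <- length(x)
  stopifnot(n >= 2L)
  (rank(x, ties.method = "average") - 1) / (n - 1)
}

#' Decile classes of percent ranks
#'
#' Classes 1-10, each spanning 10% of the percent-rank scale (class 10 is the
#' top decile of habitat selection).
#'
#' @param pr percent ranks in [0, 1].
#' @return integer classes 1-10.
#' @export
decile_class <- function(pr) {
  pmin(10L, pmax(1L, as.integer(floor(pr * 10) + 1L)))
}

#' Combine standardized species maps into a multi-species composite
#'
#' Cellwise mean of the per-species standardized (equal-contribution) maps,
#' then percent ranks and decile classes for mapping.
#'
#' @param species_maps named list of per-species standardized vectors (from
#'   `standardize_predictions()$overall`), identical grids.
#' @return data.frame `composite`, `percent_rank`, `decile`.
#' @export
composite_multispecies <- function(species_maps) {
  stopifnot(length(species_maps) >= 1L)
  n <- unique(vapply(species_maps, length, 0L))
  if (length(n) != 1L) stop("species maps are on different grids")
  comp <- rowMeans(do.call(cbind, species_maps))
  pr <- percent_rank(comp)
  data.frame(composite = comp, percent_rank = pr, decile = decile_class(pr))
}

#' Monthly habitat-use maps for selected months
#'
#' One decile-classed map per species per requested month (the months most
#' consistently surveyed: May, July, September). Absent months are skipped
#' with a warning.
#'
#' @param std a [standardize_predictions()] result.
#' @param months calendar months to map.
#' @return named list (by month) of data.frames `value`, `percent_rank`,
#'   `decile`; empty (with a warning) if no months match.
#' @export
monthly_maps <- function(std, months = c(5, 7, 9)) {
  avail <- as.integer(colnames(std$monthly))
  use <- intersect(months, avail)
  if (length(use) < length(months))
    warning("months absent from predictions: ",
            paste(setdiff(months, avail), collapse = ", "))
  out <- lapply(use, function(mo) {
    v <- std$monthly[, as.character(mo)]
    pr <- percent_rank(v)
    data.frame(value = v, percent_rank = pr, decile = decile_class(pr))
  })
  names(out) <- use
  out
}
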