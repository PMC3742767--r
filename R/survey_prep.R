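# From raw track/sighting records to the binned model table: 3-km bins laid
# from the western terminus, behavior-filtered count aggregation, distance
# covariates, surface-fluorescence gap-fill regression, and climate-index
# attachment.

#' Break an along-track length into 3-km bins
#'
#' Consecutive bins from the transect start; the terminal remainder is kept
#' only if it is at least 1 km long (shorter stubs are discarded).
#'
#' @param length_km transect length in km.
#' @param bin_km nominal bin length (default 3).
#' @param min_km minimum length a terminal remainder must have to be kept.
#' @return data.frame with columns `start`, `end` (km); zero rows for a
#'   transect shorter than `min_km`.
#' @export
bin_breaks <- function(length_km, bin_km = 3, min_km = 1) {
  if (length_km < min_km) return(data.frame(start = numeric(), end = numeric()))
  n_full <- floor(length_km / bin_km)
  starts <- seq_len(n_full) * bin_km - bin_km
  ends <- starts + bin_km
  rem <- length_km - n_full * bin_km
  if (rem >= min_km) {
    starts <- c(starts, n_full * bin_km)
    ends <- c(ends, length_km)
  }
  data.frame(start = starts, end = ends)
}

#' Bin effort records into 3-km transect bins
#'
#' Bins are laid from the transect's western terminus (the track is
#' parameterized by monotone along-track distance); each bin is represented
#' by its along-track midpoint. Detection conditions are taken from the
#' effort segment covering the midpoint; the clock time is the time the bin
#' was completed; the surveyed area is length x strip width.
#'
#' @param effort effort data.frame from [generate_transect_survey()] (or real
#'   data in the same dictionary: per-segment `cruise_id`, `transect_id`,
#'   `seg_start_km`, `seg_end_km`, `x_start`, `x_end`, `y`, `strip_width_m`,
#'   condition columns, `time`).
#' @param bin_km bin length in km (default 3).
#' @return data.frame of transect bins (`cruise_id`, `year`, `month`,
#'   `transect_id`, `bin`, `start_km`, `end_km`, `length_km`, `x`, `y`,
#'   `strip_width_m`, `area_km2`, conditions). Transects shorter than 1 km
#'   produce no bins, with a warning.
#' @export
bin_transects <- function(effort, bin_km = 3) {
  out <- list()
  for (key in split(seq_len(nrow(effort)),
                    paste(effort$cruise_id, effort$transect_id))) {
    seg <- effort[key, ]
    seg <- seg[order(seg$seg_start_km), ]
    len <- max(seg$seg_end_km)
    brk <- bin_breaks(len, bin_km)
    if (nrow(brk) == 0L) {
      warning("transect ", seg$transect_id[1], " on ", seg$cruise_id[1],
              " shorter than 1 km; no bins")
      next
    }
    mid <- (brk$start + brk$end) / 2
    # segment covering a given along-track km
    seg_at <- function(km) {
      idx <- findInterval(pmin(km, len - 1e-9), seg$seg_start_km)
      pmax(1L, idx)
    }
    mi <- seg_at(mid); ei <- seg_at(brk$end - 1e-9)
    x0 <- min(seg$x_start)
    dirn <- sign(seg$x_end[nrow(seg)] - seg$x_start[1])
    if (dirn == 0) dirn <- 1
    bins <- data.frame(
      cruise_id = seg$cruise_id[1], year = seg$year[1], month = seg$month[1],
      transect_id = seg$transect_id[1], bin = seq_len(nrow(brk)),
      start_km = brk$start, end_km = brk$end, length_km = brk$end - brk$start,
      x = seg$x_start[1] + dirn * mid * 1000, y = seg$y[1],
      strip_width_m = seg$strip_width_m[mi],
      seastate = seg$seastate[mi], cloud = seg$cloud[mi],
      visibility = seg$visibility[mi], swell_m = seg$swell_m[mi],
      time = seg$time[ei])
    bins$area_km2 <- bins$length_km * bins$strip_width_m / 1000
    out[[length(out) + 1L]] <- bins
  }
  do.call(rbind, out)
}

#' Aggregate sightings to per-bin, per-species counts
#'
#' Only foraging, feeding and sitting records are used (flying and
#' ship-attract birds are excluded); group sizes are summed by species within
#' the bin covering the sighting's along-track position, with boundary ties
#' going to the earlier bin. Sightings falling outside every bin (e.g. on a
#' discarded terminal stub) are excluded and reported.
#'
#' @param sightings sightings data.frame (`sighting_id`, `cruise_id`,
#'   `transect_id`, `species`, `along_km`, `group_size`, `behavior`).
#' @param bins bin table from [bin_transects()].
#' @param behaviors behaviors retained for analysis.
#' @return list with `counts` (matrix bins x species), `exclusions`
#'   (data.frame report: behavior-filtered and out-of-bin tallies).
#' @export
aggregate_counts <- function(sightings, bins,
                             behaviors = c("foraging", "feeding", "sitting")) {
  if (anyDuplicated(sightings$sighting_id))
    stop("duplicate sighting ids")
  species <- sort(unique(sightings$species))
  counts <- matrix(0L, nrow(bins), length(species),
                   dimnames = list(NULL, species))
  keep <- sightings$behavior %in% behaviors
  retained <- sightings[keep, ]
  n_out <- 0L
  if (nrow(retained) > 0L) {
    bin_key <- paste(bins$cruise_id, bins$transect_id)
    for (i in seq_len(nrow(retained))) {
      s <- retained[i, ]
      cand <- which(bin_key == paste(s$cruise_id, s$transect_id) &
                      bins$start_km < s$along_km + 1e-12 &
                      bins$end_km >= s$along_km - 1e-12)
      # ties at a shared boundary go to the earlier bin
      if (length(cand) == 0L) { n_out <- n_out + 1L; next }
      b <- cand[which.min(bins$bin[cand])]
      counts[b, s$species] <- counts[b, s$species] + s$group_size
    }
  }
  exclusions <- data.frame(
    reason = c("behavior_filtered", "outside_bins"),
    n_records = c(sum(!keep), n_out))
  list(counts = counts, exclusions = exclusions)
}

#' Distance covariates from bin midpoints
#'
#' Planar Euclidean distances from each bin midpoint to the nearest point of
#' the mainland coastline, the 200-m isobath (shelf break), and the island
#' colony.
#'
#' @param bins bin table with midpoint columns `x`, `y`.
#' @param region a [study_region()].
#' @return `bins` with `dist_land`, `dist_200`, `dist_sefi` columns (meters).
#' @export
compute_distances <- function(bins, region) {
  for (layer in c("mainland", "isobath_200")) {
    if (is.null(region[[layer]]) || nrow(coerce_xy(region[[layer]])) == 0L)
      stop("missing region layer: ", layer)
  }
  pts <- cbind(bins$x, bins$y)
  bins$dist_land <- dist_to_polyline(pts, region$mainland)
  bins$dist_200 <- dist_to_polyline(pts, region$isobath_200)
  bins$dist_sefi <- dist_to_polyline(pts, matrix(region$colony, ncol = 2))
  bins
}

#' Gap-fill missing surface fluorescence from CTD records
#'
#' Ordinary least squares of station-level 1-6-m fluorescence on station SST
#' and year, fitted on the CTD records and applied only to bins whose SSF is
#' missing (cruises without a thermosalinograph). With a single year of CTD
#' data the design is rank-deficient in year and an SST-only regression is
#' used, with a warning.
#'
#' @param bins bin table with an `ssf` column (NA where missing) and `sst`,
#'   `year`.
#' @param ctd CTD data.frame from [generate_ctd_stations()] (`ssf_1_6m`,
#'   `sst`, `year`).
#' @return list with `bins` (SSF filled, logical `ssf_imputed` flag),
#'   `fit` (coefficients, `r_squared`, `n_ctd`, `n_imputed`).
#' @export
fill_missing_ssf <- function(bins, ctd) {
  miss <- is.na(bins$ssf)
  if (!any(miss)) {
    bins$ssf_imputed <- FALSE
    return(list(bins = bins, fit = list(coefficients = NULL, r_squared = NA,
                                        n_ctd = nrow(ctd), n_imputed = 0L)))
  }
  if (is.null(ctd) || nrow(ctd) == 0L)
    stop("no CTD records available to gap-fill missing SSF")
  if (nrow(ctd) < 10L) stop("need >= 10 CTD records to fit the gap-fill regression")
  if (length(unique(ctd$year)) < 2L) {
    warning("single CTD year: falling back to SST-only gap-fill regression")
    fit <- stats::lm(ssf_1_6m ~ sst, data = ctd)
  } else {
    fit <- stats::lm(ssf_1_6m ~ sst + year, data = ctd)
  }
  pred <- stats::predict(fit, newdata = bins[miss, , drop = FALSE])
  bins$ssf[miss] <- pmax(0, pred)
  bins$ssf_imputed <- miss
  list(bins = bins,
       fit = list(coefficients = stats::coef(fit),
                  r_squared = summary(fit)$r.squared,
                  n_ctd = nrow(ctd), n_imputed = sum(miss)))
}

#' Attach climate indices and the upwelling average to bins
#'
#' Every bin of a cruise gets that cruise's monthly NPGO/PDO/SOI values and
#' the upwelling index as the arithmetic mean of exactly the 10 daily values
#' ending on the cruise's last survey day.
#'
#' @param bins bin table with `cruise_id`, `year`, `month`.
#' @param monthly data.frame `year`, `month`, `npgo`, `pdo`, `soi`.
#' @param daily data.frame `date`, `ui`.
#' @param calendar cruise calendar with `cruise_id`, `year`, `month`,
#'   `end_day`.
#' @return `bins` with `npgo`, `pdo`, `soi`, `ui` columns.
#' @export
attach_indices <- function(bins, monthly, daily, calendar) {
  bins$npgo <- bins$pdo <- bins$soi <- bins$ui <- NA_real_
  for (i in seq_len(nrow(calendar))) {
    cid <- calendar$cruise_id[i]
    sel <- bins$cruise_id == cid
    if (!any(sel)) next
    m <- monthly[monthly$year == calendar$year[i] &
                   monthly$month == calendar$month[i], ]
    if (nrow(m) == 0L)
      stop(sprintf("missing monthly index for (%d, %d)",
                   calendar$year[i], calendar$month[i]))
    end_date <- as.Date(sprintf("%d-%02d-%02d", calendar$year[i],
                                calendar$month[i], calendar$end_day[i]))
    win <- daily[daily$date > end_date - 10 & daily$date <= end_date, ]
    if (nrow(win) != 10L)
      stop(sprintf("need exactly 10 daily upwelling values before (%d, %d)",
                   calendar$year[i], calendar$month[i]))
    bins$npgo[sel] <- m$npgo; bins$pdo[sel] <- m$pdo; bins$soi[sel] <- m$soi
    bins$ui[sel] <- mean(win$ui)
  }
  bins
}

#' Assemble the binned model table from a simulated survey
#'
#' Runs the full preparation chain: 3-km binning, behavior-filtered count
#' aggregation, surface-field sampling at midpoints (with SSF withheld on
#' cruises lacking a thermosalinograph), distance covariates, CTD gap-fill of
#' SSF, and climate-index attachment. Bins missing SST or SSS are dropped and
#' the drop is reported.
#'
#' @param sim a `survey_bundle` from [simulate_survey()].
#' @param bin_km bin length (km).
#' @return list with `table` (the model table, one row per bin with counts
#'   and covariates), `exclusions`, `ssf_fit` (gap-fill regression summary),
#'   `n_dropped_sst_sss`.
#' @export
build_model_table <- function(sim, bin_km = 3) {
  bins <- bin_transects(sim$survey$effort, bin_km)
  agg <- aggregate_counts(sim$survey$sightings, bins)
  bins <- cbind(bins, agg$counts)
  bins <- compute_distances(bins, sim$region)
  pts <- cbind(bins$x, bins$y)
  bins$sst <- NA_real_; bins$sss <- NA_real_; bins$ssf <- NA_real_
  for (i in seq_len(nrow(sim$survey$cruises))) {
    cr <- sim$survey$cruises[i, ]
    sel <- bins$cruise_id == cr$cruise_id
    if (!any(sel)) next
    p <- pts[sel, , drop = FALSE]
    bins$sst[sel] <- field_eval(sim$fields[[cr$cruise_id]]$sst, p)
    bins$sss[sel] <- field_eval(sim$fields[[cr$cruise_id]]$sss, p)
    if (!cr$ssf_missing)
      bins$ssf[sel] <- field_eval(sim$fields[[cr$cruise_id]]$ssf, p)
  }
  n_drop <- sum(is.na(bins$sst) | is.na(bins$sss))
  bins <- bins[!(is.na(bins$sst) | is.na(bins$sss)), ]
  filled <- fill_missing_ssf(bins, sim$ctd)
  bins <- attach_indices(filled$bins, sim$indices$monthly, sim$indices$daily,
                         sim$region$calendar)
  list(table = bins, exclusions = agg$exclusions, ssf_fit = filled$fit,
       n_dropped_sst_sss = n_drop)
}
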