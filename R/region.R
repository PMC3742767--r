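#' Study region for survey simulation and prediction
#'
#' Bundles the geographic referents the pipeline needs: the sanctuary-like
#' study boundary, the island colony point (the "SEFI" referent for
#' distance-to-colony), the mainland coastline, the 200-m isobath marking the
#' shelf break, and the cruise calendar. All geometry lives in one local
#' planar frame in meters; no geodesy is attempted.
#'
#' @param boundary polygon ring (n x 2 matrix, meters), simple and closed.
#' @param colony length-2 numeric, colony location; must lie inside `boundary`.
#' @param mainland polyline (m x 2 matrix) for distance-to-land.
#' @param isobath_200 polyline for distance-to-shelf-break.
#' @param calendar data.frame with columns `year`, `month`, `end_day`
#'   (the cruise's last survey day); one row per cruise, >= 1 row.
#' @return an object of class `study_region`.
#' @export
study_region <- function(boundary, colony, mainland, isobath_200, calendar) {
  boundary <- coerce_xy(boundary)
  if (nrow(boundary) < 3L) stop("boundary must have >= 3 vertices")
  if (!point_in_polygon(matrix(colony, ncol = 2), boundary))
    stop("colony must lie inside the study boundary")
  stopifnot(is.data.frame(calendar), nrow(calendar) >= 1L,
            all(c("year", "month") %in% names(calendar)))
  if (is.null(calendar$end_day)) calendar$end_day <- 15L
  calendar$cruise_id <- sprintf("C%02d", seq_len(nrow(calendar)))
  structure(list(boundary = boundary, colony = as.numeric(colony),
                 mainland = coerce_xy(mainland),
                 isobath_200 = coerce_xy(isobath_200),
                 calendar = calendar),
            class = "study_region")
}

#' @export
print.study_region <- function(x, ...) {
  bb <- apply(x$boundary, 2, range)
  cat("study_region:", nrow(x$calendar), "cruises,",
      sprintf("extent %.0f x %.0f km\n",
              diff(bb[, 1]) / 1000, diff(bb[, 2]) / 1000))
  invisible(x)
}

#' Default synthetic study region
#'
#' A 40 x 55 km coastal rectangle (about 2200 km2, the scale of the combined
#' Gulf of the Farallones and Cordell Bank sanctuaries), with the mainland
#' along the eastern edge, a shelf-break isobath running north-south through
#' the western third, an offshore island colony, and a calendar of 27 cruises
#' over 2004-2011 in April-September (May, July and September sampled every
#' year, matching the months the mapping stage focuses on).
#'
#' @param n_cruises number of cruises to keep from the default 27-entry
#'   calendar (from the top).
#' @return a `study_region`.
#' @export
default_region <- function(n_cruises = 27) {
  boundary <- rbind(c(0, 0), c(40000, 0), c(40000, 55000), c(0, 55000))
  colony <- c(26000, 24000)
  mainland <- rbind(c(40000, -20000), c(40000, 75000))
  isobath <- rbind(c(12000, -20000), c(13500, 18000), c(11000, 40000),
                   c(12500, 75000))
  months_by_year <- list(
    `2004` = c(4, 5, 7, 9), `2005` = c(5, 6, 7, 9), `2006` = c(5, 7, 8, 9),
    `2007` = c(5, 7, 9), `2008` = c(5, 7, 9), `2009` = c(5, 7, 9),
    `2010` = c(5, 7, 9), `2011` = c(5, 7, 9))
  calendar <- do.call(rbind, lapply(names(months_by_year), function(y) {
    data.frame(year = as.integer(y), month = months_by_year[[y]])
  }))
  calendar$end_day <- 15L
  stopifnot(nrow(calendar) == 27L)
  n_cruises <- min(n_cruises, nrow(calendar))
  study_region(boundary, colony, mainland, isobath,
               calendar[seq_len(n_cruises), ])
}

#' Write a study region (or activity footprints) to GeoJSON
#'
#' Plain GeoJSON FeatureCollection in the local planar frame (coordinates are
#' meters, not longitude/latitude).
#'
#' @param region a `study_region`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_region_geojson <- function(region, path) {
  close_ring <- function(m) rbind(m, m[1, , drop = FALSE])
  feat <- function(geom_type, coords, props) {
    list(type = "Feature", properties = props,
         geometry = list(type = geom_type, coordinates = coords))
  }
  mat2list <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  fc <- list(type = "FeatureCollection", features = list(
    feat("Polygon", list(mat2list(close_ring(region$boundary))),
         list(name = "boundary")),
    feat("Point", as.numeric(region$colony), list(name = "colony")),
    feat("LineString", mat2list(region$mainland), list(name = "mainland")),
    feat("LineString", mat2list(region$isobath_200), list(name = "isobath_200"))
  ))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
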