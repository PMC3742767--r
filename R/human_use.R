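# General human-use cost layer: summed 1-5 impact scores of dominant-use
# activity footprints over grid cells.

#' Score grid cells by overlapping activity footprints
#'
#' A cell's score is the sum of impact scores of all activities whose
#' dominant-use polygon overlaps the cell square (any shared area counts, not
#' just centroid containment). With the six default-scored activities the
#' maximum possible cell score is 17.
#'
#' @param cells grid from [build_grid()] (centroids `x`, `y`; square cells of
#'   side `sqrt(area_km2) * 1000` m).
#' @param activities an `activity_set` from [generate_human_activities()] or
#'   [read_activities_geojson()]; only `class == "dominant"` footprints are
#'   costed. Activity names must be among the six expected.
#' @return `cells` with a `human_use` column (integer score per cell).
#' @export
score_cells <- function(cells, activities) {
  expected <- activity_scores()$activity
  nm <- vapply(activities, `[[`, "", "activity")
  bad <- setdiff(nm, expected)
  if (length(bad) > 0L)
    stop("unknown activity name(s): ", paste(bad, collapse = ", "),
         "; expected one of: ", paste(expected, collapse = ", "))
  half <- sqrt(cells$area_km2) * 1000 / 2
  score <- integer(nrow(cells))
  for (a in activities) {
    if (!identical(a$class, "dominant")) next
    poly <- coerce_xy(a$polygon)
    # cheap prefilter on the polygon bounding box, exact test after
    bx <- range(poly[, 1]); by <- range(poly[, 2])
    cand <- which(cells$x + half >= bx[1] & cells$x - half <= bx[2] &
                    cells$y + half >= by[1] & cells$y - half <= by[2])
    for (i in cand) {
      if (polygon_rect_overlap(poly, cells$x[i] - half[i], cells$x[i] + half[i],
                               cells$y[i] - half[i], cells$y[i] + half[i]))
        score[i] <- score[i] + a$score
    }
  }
  cells$human_use <- score
  cells
}

#' Quintile classes of the human-use layer
#'
#' Five classes each spanning 20% of the maximum observed score (the map
#' convention of 20% gradients).
#'
#' @param score per-cell human-use scores.
#' @return integer classes 1-5 (0 stays 0-scored in class 1).
#' @export
human_use_quintiles <- function(score) {
  mx <- max(score)
  if (mx == 0) return(rep(1L, length(score)))
  pmin(5L, pmax(1L, as.integer(ceiling(score / mx * 5))))
}
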