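# Planar geometry helpers. All coordinates are meters in one local planar
# frame; polygons are closed rings given as n x 2 matrices (first vertex not
# repeated), polylines are n x 2 matrices of ordered vertices.

#' Test whether points lie inside a polygon
#'
#' Even-odd ray casting with points exactly on an edge counted as inside
#' (closed-boundary convention, used for grid-cell inclusion).
#'
#' @param pts n x 2 matrix of point coordinates (meters).
#' @param poly polygon ring as an m x 2 matrix, not closed.
#' @return logical vector of length n.
#' @export
point_in_polygon <- function(pts, poly) {
  pts <- coerce_xy(pts)
  poly <- coerce_xy(poly)
  n <- nrow(pts)
  m <- nrow(poly)
  if (m < 3L) stop("polygon needs >= 3 vertices")
  inside <- rep(FALSE, n)
  x <- pts[, 1]; y <- pts[, 2]
  j <- m
  for (i in seq_len(m)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  # boundary points count as inside
  on_edge <- rep(FALSE, n)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    d <- dist_point_segment(pts, poly[i, ], poly[j, ])
    on_edge <- on_edge | d < 1e-9
  }
  inside | on_edge
}

#' Distance from points to a line segment
#'
#' @param pts n x 2 matrix.
#' @param a,b segment endpoints, length-2 numeric.
#' @return numeric vector of Euclidean distances.
#' @keywords internal
dist_point_segment <- function(pts, a, b) {
  pts <- coerce_xy(pts)
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  }
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  px <- a[1] + t * ab[1]
  py <- a[2] + t * ab[2]
  sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
}

#' Distance from points to a polyline
#'
#' Minimum Euclidean distance from each point to any segment of the polyline.
#'
#' @param pts n x 2 matrix.
#' @param line polyline as an m x 2 matrix (m >= 2) or a single point (m = 1).
#' @return numeric vector of distances (meters).
#' @export
dist_to_polyline <- function(pts, line) {
  pts <- coerce_xy(pts)
  line <- coerce_xy(line)
  if (nrow(line) == 0L) stop("empty geometry")
  if (nrow(line) == 1L) return(dist_point_segment(pts, line[1, ], line[1, ]))
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(line) - 1L)) {
    d <- pmin(d, dist_point_segment(pts, line[i, ], line[i + 1L, ]))
  }
  d
}

#' Distance from points to a polygon (0 inside)
#'
#' @param pts n x 2 matrix.
#' @param poly polygon ring m x 2.
#' @return numeric vector; 0 for points inside or on the boundary.
#' @export
dist_to_polygon <- function(pts, poly) {
  pts <- coerce_xy(pts)
  ring <- rbind(poly, poly[1, , drop = FALSE])
  d <- dist_to_polyline(pts, ring)
  d[point_in_polygon(pts, poly)] <- 0
  d
}

# do two segments (a1-a2, b1-b2) intersect (including touching)?
segments_intersect <- function(a1, a2, b1, b2) {
  orient <- function(p, q, r) {
    v <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    if (abs(v) < 1e-12) 0 else sign(v)
  }
  on_seg <- function(p, q, r) {
    min(p[1], q[1]) - 1e-12 <= r[1] && r[1] <= max(p[1], q[1]) + 1e-12 &&
      min(p[2], q[2]) - 1e-12 <= r[2] && r[2] <= max(p[2], q[2]) + 1e-12
  }
  o1 <- orient(a1, a2, b1); o2 <- orient(a1, a2, b2)
  o3 <- orient(b1, b2, a1); o4 <- orient(b1, b2, a2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on_seg(a1, a2, b1)) || (o2 == 0 && on_seg(a1, a2, b2)) ||
    (o3 == 0 && on_seg(b1, b2, a1)) || (o4 == 0 && on_seg(b1, b2, a2))
}

#' Does a polygon overlap an axis-aligned rectangle?
#'
#' Any shared area or touching counts as overlap (used for scoring activity
#' footprints onto grid cells).
#'
#' @param poly polygon ring m x 2.
#' @param xmin,xmax,ymin,ymax rectangle bounds.
#' @return logical scalar.
#' @export
polygon_rect_overlap <- function(poly, xmin, xmax, ymin, ymax) {
  poly <- coerce_xy(poly)
  # polygon vertex inside rectangle
  if (any(poly[, 1] >= xmin & poly[, 1] <= xmax &
            poly[, 2] >= ymin & poly[, 2] <= ymax)) return(TRUE)
  corners <- rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax))
  if (any(point_in_polygon(corners, poly))) return(TRUE)
  m <- nrow(poly)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    for (k in 1:4) {
      l <- if (k == 4L) 1L else k + 1L
      if (segments_intersect(poly[i, ], poly[j, ], corners[k, ], corners[l, ]))
        return(TRUE)
    }
  }
  FALSE
}

coerce_xy <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}
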