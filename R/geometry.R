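# Planar geometry primitives.
#
# All coordinates are metres in a local planar frame (the study distances --
# 30 m buffers, 10 m pixels -- are small enough that geodesy is unnecessary).
# Polygons are n x 2 matrices of vertices, implicitly closed; polylines are
# n x 2 matrices of consecutive vertices.

#' Point-in-polygon test
#'
#' Even-odd ray-casting test. Points exactly on an edge are treated as
#' inside (distance-zero containment), which keeps buffered containment
#' monotone in the buffer width.
#'
#' @param px,py point coordinates (vectors of equal length).
#' @param poly n x 2 vertex matrix, implicitly closed.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- logical(length(px))
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ye[i] > py))
    if (any(crosses)) {
      xint <- xs[i] + (py - ys[i]) / (ye[i] - ys[i]) * (xe[i] - xs[i])
      flip <- crosses & (px < xint)
      inside[flip] <- !inside[flip]
    }
  }
  # on-edge points count as inside
  on_edge <- dist_to_polyline(px, py, rbind(poly, poly[1, , drop = FALSE])) <
    1e-9
  inside | on_edge
}

# Distance from points to a single segment (x1,y1)-(x2,y2).
dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Distance from points to a polyline
#'
#' @param px,py point coordinates.
#' @param line n x 2 vertex matrix of a polyline (not closed).
#' @return Numeric vector of Euclidean distances in metres.
#' @export
dist_to_polyline <- function(px, py, line) {
  stopifnot(is.matrix(line), ncol(line) == 2, nrow(line) >= 2)
  d <- rep(Inf, length(px))
  for (i in seq_len(nrow(line) - 1L)) {
    d <- pmin(d, dist_point_segment(px, py, line[i, 1], line[i, 2],
                                    line[i + 1, 1], line[i + 1, 2]))
  }
  d
}

#' Signed distance from points to a polygon
#'
#' Zero inside or on the boundary, the boundary distance outside. Used for
#' buffered containment: a point is within a polygon buffered by `b` iff
#' `dist_to_polygon(...) <= b`.
#'
#' @inheritParams point_in_polygon
#' @return Numeric vector (>= 0).
#' @export
dist_to_polygon <- function(px, py, poly) {
  d <- dist_to_polyline(px, py, rbind(poly, poly[1, , drop = FALSE]))
  d[point_in_polygon(px, py, poly)] <- 0
  d
}

# Regular polygon approximating an ellipse, used for synthetic estuaries.
ellipse_polygon <- function(cx, cy, rx, ry, n = 72, rotate = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x0 <- rx * cos(th); y0 <- ry * sin(th)
  cbind(cx + x0 * cos(rotate) - y0 * sin(rotate),
        cy + x0 * sin(rotate) + y0 * cos(rotate))
}
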