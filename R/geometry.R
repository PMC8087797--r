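# Planar geometry primitives (Cartesian coordinates in km).
#
# Polygons are numeric matrices with columns (x, y); the closing edge from the
# last vertex back to the first is implicit. Multipolygons are unclassed lists
# of such matrices with pairwise-disjoint interiors, so areas and clipped
# lengths are additive over the pieces. All internal polygon-on-polygon
# operations clip AGAINST a convex polygon (Sutherland-Hodgman); the synthetic
# generators only ever emit convex pieces, which keeps that route exact.

#' Polygon area by the shoelace formula
#'
#' @param poly Numeric matrix with columns x, y (vertices in order, open ring).
#' @return Area in km^2 (always non-negative).
#' @export
polygon_area <- function(poly) {
  if (is.list(poly)) return(sum(vapply(poly, polygon_area, numeric(1))))
  if (is.null(poly) || nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Polygon centroid
#' @param poly Polygon matrix.
#' @return Numeric length-2 vector (x, y).
#' @keywords internal
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Test points for inclusion in a polygon (ray casting)
#'
#' Boundary points count as inside. Vectorised over points.
#'
#' @param px,py Numeric vectors of point coordinates.
#' @param poly Polygon matrix or multipolygon list.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  if (is.list(poly)) {
    res <- rep(FALSE, length(px))
    for (p in poly) res <- res | point_in_polygon(px, py, p)
    return(res)
  }
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # boundary check: point collinear with and within edge bbox
    dx <- xj - xi; dy <- yj - yi
    cross <- (px - xi) * dy - (py - yi) * dx
    within <- pmin(xi, xj) - 1e-12 <= px & px <= pmax(xi, xj) + 1e-12 &
      pmin(yi, yj) - 1e-12 <= py & py <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | (abs(cross) < 1e-9 & within)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Clip a polygon against a convex polygon (Sutherland-Hodgman)
#'
#' @param subject Polygon matrix (any simple polygon).
#' @param clip Polygon matrix; must be convex.
#' @return Polygon matrix of the intersection, or NULL if empty.
#' @export
clip_polygon_convex <- function(subject, clip) {
  if (is.null(subject) || nrow(subject) < 3) return(NULL)
  # ensure counter-clockwise clip ring so "inside" is left of each edge
  if (signed_area(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (is.null(out) || nrow(out) < 3) return(NULL)
    a <- clip[e, ]; b <- clip[if (e == nc) 1 else e + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    side <- (out[, 1] - a[1]) * ey - (out[, 2] - a[2]) * ex
    inside <- side <= 1e-12  # left of edge (ccw) or on it
    n <- nrow(out)
    nxt <- c(2:n, 1)
    newx <- numeric(0); newy <- numeric(0)
    for (i in seq_len(n)) {
      j <- nxt[i]
      if (inside[i]) { newx <- c(newx, out[i, 1]); newy <- c(newy, out[i, 2]) }
      if (inside[i] != inside[j]) {
        t <- side[i] / (side[i] - side[j])
        newx <- c(newx, out[i, 1] + t * (out[j, 1] - out[i, 1]))
        newy <- c(newy, out[i, 2] + t * (out[j, 2] - out[i, 2]))
      }
    }
    out <- if (length(newx) >= 3) cbind(x = newx, y = newy) else NULL
  }
  if (!is.null(out) && polygon_area(out) < 1e-12) out <- NULL
  out
}

#' Area of the intersection of a polygon/multipolygon with a convex polygon
#' @param poly Polygon matrix or multipolygon list.
#' @param clip Convex polygon matrix.
#' @return Area in km^2.
#' @export
intersection_area_convex <- function(poly, clip) {
  if (is.list(poly)) {
    return(sum(vapply(poly, intersection_area_convex, numeric(1), clip = clip)))
  }
  polygon_area(clip_polygon_convex(poly, clip))
}

signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

#' Check that a polygon ring is simple (no self-intersection)
#' @param poly Polygon matrix.
#' @return TRUE/FALSE.
#' @export
is_simple_polygon <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  seg <- cbind(poly, poly[c(2:n, 1), ])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next  # adjacent edges share a vertex
      if (segments_intersect(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

# proper or improper intersection of closed segments p1-p2 and p3-p4
segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- cross3(p3, p4, p1); d2 <- cross3(p3, p4, p2)
  d3 <- cross3(p1, p2, p3); d4 <- cross3(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  eps <- 1e-12
  (abs(d1) < eps && on_segment(p3, p4, p1)) ||
    (abs(d2) < eps && on_segment(p3, p4, p2)) ||
    (abs(d3) < eps && on_segment(p1, p2, p3)) ||
    (abs(d4) < eps && on_segment(p1, p2, p4))
}

cross3 <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])

on_segment <- function(a, b, p) {
  min(a[1], b[1]) - 1e-12 <= p[1] && p[1] <= max(a[1], b[1]) + 1e-12 &&
    min(a[2], b[2]) - 1e-12 <= p[2] && p[2] <= max(a[2], b[2]) + 1e-12
}

#' Length of a polyline
#' @param coords Matrix with columns x, y.
#' @return Length in km.
#' @export
polyline_length <- function(coords) {
  if (nrow(coords) < 2) return(0)
  sum(sqrt(diff(coords[, 1])^2 + diff(coords[, 2])^2))
}

#' Length of the part of a polyline inside a simple polygon
#'
#' Exact parametric clip: each segment is cut at its crossings with every
#' polygon edge and sub-segment midpoints are classified by point-in-polygon.
#' Works for arbitrary simple polygons and multipolygons (disjoint pieces sum).
#'
#' @param coords Polyline matrix (columns x, y).
#' @param poly Polygon matrix or multipolygon list of disjoint pieces.
#' @return Clipped length in km.
#' @export
polyline_length_in_polygon <- function(coords, poly) {
  if (is.list(poly)) {
    return(sum(vapply(poly, function(p) polyline_length_in_polygon(coords, p),
                      numeric(1))))
  }
  if (nrow(coords) < 2) return(0)
  n <- nrow(poly)
  ex1 <- poly[, 1]; ey1 <- poly[, 2]
  ex2 <- poly[c(2:n, 1), 1]; ey2 <- poly[c(2:n, 1), 2]
  total <- 0
  for (s in seq_len(nrow(coords) - 1)) {
    ax <- coords[s, 1]; ay <- coords[s, 2]
    bx <- coords[s + 1, 1]; by <- coords[s + 1, 2]
    dx <- bx - ax; dy <- by - ay
    len <- sqrt(dx^2 + dy^2)
    if (len < 1e-15) next
    # solve a + t*d crossing each polygon edge
    rx <- ex2 - ex1; ry <- ey2 - ey1
    denom <- dx * ry - dy * rx
    qx <- ex1 - ax; qy <- ey1 - ay
    t <- (qx * ry - qy * rx) / denom
    u <- (qx * dy - qy * dx) / denom
    ok <- is.finite(t) & t > 0 & t < 1 & u >= 0 & u <= 1
    ts <- sort(unique(c(0, t[ok], 1)))
    mid_t <- (ts[-1] + ts[-length(ts)]) / 2
    inside <- point_in_polygon(ax + mid_t * dx, ay + mid_t * dy, poly)
    total <- total + len * sum(diff(ts)[inside])
  }
  unname(total)
}

#' Generate a random convex polygon of a given area
#'
#' Vertices are drawn on a jittered radial fan around a centre, hulled, and
#' scaled to the target area. Used by the burn-scar generator.
#'
#' @param center Length-2 numeric, polygon centre (km).
#' @param area_km2 Target area.
#' @param n_vertices Number of radial samples before hulling.
#' @return Convex polygon matrix with exactly the requested area.
#' @export
random_convex_polygon <- function(center, area_km2, n_vertices = 10) {
  stopifnot(area_km2 > 0)
  center <- unname(center)
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  rad <- stats::rgamma(n_vertices, shape = 6, rate = 6)
  pts <- cbind(cos(ang) * rad, sin(ang) * rad)
  hull <- grDevices::chull(pts)
  pts <- pts[hull, , drop = FALSE]
  a0 <- polygon_area(pts)
  pts <- pts * sqrt(area_km2 / a0)
  ctr <- polygon_centroid(pts)
  cbind(x = pts[, 1] - ctr[1] + center[1], y = pts[, 2] - ctr[2] + center[2])
}

#' Split a convex polygon into patches of prescribed area fractions
#'
#' Cuts with vertical lines found by bisection so piece areas match the
#' requested fractions of the total area; every piece is convex.
#'
#' @param poly Convex polygon matrix.
#' @param fractions Non-negative fractions summing to 1.
#' @return List of polygon matrices, one per positive fraction, in order;
#'   zero fractions yield NULL entries.
#' @export
split_polygon_by_fractions <- function(poly, fractions) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, all(fractions >= 0))
  total <- polygon_area(poly)
  xmin <- min(poly[, 1]); xmax <- max(poly[, 1])
  # area of polygon left of vertical line x = c
  left_area <- function(cx) {
    clipper <- cbind(x = c(xmin - 1, cx, cx, xmin - 1),
                     y = c(min(poly[, 2]) - 1, min(poly[, 2]) - 1,
                           max(poly[, 2]) + 1, max(poly[, 2]) + 1))
    intersection_area_convex(poly, clipper)
  }
  cuts <- xmin
  cum <- cumsum(fractions)
  for (f in cum[-length(cum)]) {
    target <- f * total
    lo <- xmin; hi <- xmax
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      if (left_area(mid) < target) lo <- mid else hi <- mid
    }
    cuts <- c(cuts, (lo + hi) / 2)
  }
  cuts <- c(cuts, xmax)
  ymin <- min(poly[, 2]) - 1; ymax <- max(poly[, 2]) + 1
  out <- vector("list", length(fractions))
  for (i in seq_along(fractions)) {
    if (fractions[i] <= 0) next
    band <- cbind(x = c(cuts[i] - (i == 1), cuts[i + 1] + (i == length(fractions)),
                        cuts[i + 1] + (i == length(fractions)), cuts[i] - (i == 1)),
                  y = c(ymin, ymin, ymax, ymax))
    out[[i]] <- clip_polygon_convex(poly, band)
  }
  out
}

#' Axis-aligned rectangle polygon
#' @param xmin,xmax,ymin,ymax Bounds in km.
#' @return Polygon matrix.
#' @export
rect_polygon <- function(xmin, xmax, ymin, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}
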