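# Planar polygon utilities used by the mesh and quadrature code.
# Polygons are n x 2 numeric matrices of vertices in order (open ring:
# the closing edge last->first is implicit). Coordinates are planar km.

#' Coerce a polygon argument to an open n x 2 vertex matrix
#' @noRd
as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (!is.numeric(poly) || ncol(poly) != 2L)
    stop("polygon must be a numeric matrix with two columns (x, y)", call. = FALSE)
  # drop an explicit closing vertex
  n <- nrow(poly)
  if (n >= 2L && all(poly[1L, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  if (nrow(poly) < 3L) stop("polygon needs at least three distinct vertices", call. = FALSE)
  dimnames(poly) <- NULL
  poly
}

#' Signed area of a polygon (shoelace formula)
#' @noRd
polygon_signed_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

polygon_area <- function(poly) abs(polygon_signed_area(poly))

#' Longest distance between two polygon vertices
#' @noRd
polygon_diameter <- function(poly) {
  d <- stats::dist(poly)
  max(as.numeric(d))
}

#' Check that a polygon ring is simple (no self-intersections)
#'
#' Brute-force segment pair test; polygons here are small (tens of vertices).
#' @noRd
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  seg <- cbind(poly, rbind(poly[-1L, , drop = FALSE], poly[1L, , drop = FALSE]))
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (they share an endpoint)
      if (j == i + 1L || (i == 1L && j == n)) next
      p1 <- seg[i, 1:2]; p2 <- seg[i, 3:4]; p3 <- seg[j, 1:2]; p4 <- seg[j, 3:4]
      d1 <- cross(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
      d2 <- cross(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
      d3 <- cross(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
      d4 <- cross(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(FALSE)
    }
  }
  TRUE
}

#' Points in (or within tol of) a polygon
#'
#' Interior test via mgcv::in.out with an on-boundary tolerance so that mesh
#' vertices lying exactly on the window edge count as inside.
#' @noRd
points_in_polygon <- function(poly, pts, tol = 0) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  ring <- rbind(poly, poly[1L, ])
  inside <- mgcv::in.out(ring, pts)
  if (tol > 0) {
    out <- which(!inside)
    if (length(out)) {
      d <- dist_to_polyline(ring, pts[out, , drop = FALSE])
      inside[out[d <= tol]] <- TRUE
    }
  }
  inside
}

#' Distance from points to a polyline (sequence of segments)
#' @noRd
dist_to_polyline <- function(line, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  a <- line[-nrow(line), , drop = FALSE]
  b <- line[-1L, , drop = FALSE]
  ex <- b[, 1L] - a[, 1L]; ey <- b[, 2L] - a[, 2L]
  len2 <- ex^2 + ey^2
  len2[len2 == 0] <- 1e-300
  res <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    px <- pts[i, 1L]; py <- pts[i, 2L]
    tt <- ((px - a[, 1L]) * ex + (py - a[, 2L]) * ey) / len2
    tt <- pmin(pmax(tt, 0), 1)
    dx <- a[, 1L] + tt * ex - px
    dy <- a[, 2L] + tt * ey - py
    res[i] <- sqrt(min(dx^2 + dy^2))
  }
  res
}

#' Clip a polygon against a convex polygon (Sutherland-Hodgman)
#'
#' `subject` may be any simple polygon; `clip` must be convex and given
#' counter-clockwise. Returns the clipped vertex matrix (possibly 0 rows).
#' @noRd
clip_polygon_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (k in seq_len(nc)) {
    if (nrow(out) == 0L) return(out)
    a <- clip[k, ]
    b <- clip[if (k == nc) 1L else k + 1L, ]
    ex <- b[1L] - a[1L]; ey <- b[2L] - a[2L]
    # signed distance > 0 means inside (left of edge for CCW clip)
    s <- ex * (out[, 2L] - a[2L]) - ey * (out[, 1L] - a[1L])
    n <- nrow(out)
    nxt <- c(2:n, 1L)[seq_len(n)]
    keep_x <- numeric(0); keep_y <- numeric(0)
    for (i in seq_len(n)) {
      j <- nxt[i]
      si <- s[i]; sj <- s[j]
      if (si >= 0) { keep_x <- c(keep_x, out[i, 1L]); keep_y <- c(keep_y, out[i, 2L]) }
      if ((si > 0 && sj < 0) || (si < 0 && sj > 0)) {
        tt <- si / (si - sj)
        keep_x <- c(keep_x, out[i, 1L] + tt * (out[j, 1L] - out[i, 1L]))
        keep_y <- c(keep_y, out[i, 2L] + tt * (out[j, 2L] - out[i, 2L]))
      }
    }
    out <- cbind(keep_x, keep_y)
    dimnames(out) <- NULL
  }
  out
}

#' Area of the intersection of a simple polygon with a convex polygon
#' @noRd
clip_area <- function(subject, clip) {
  out <- clip_polygon_convex(subject, clip)
  if (nrow(out) < 3L) return(0)
  abs(polygon_signed_area(out))
}

#' Ensure counter-clockwise orientation
#' @noRd
ccw <- function(poly) {
  if (polygon_signed_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}
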