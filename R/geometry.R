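# Polygon primitives. Polygons are n x 2 matrices of vertices (mm), ordered
# counterclockwise, closed implicitly (last vertex connects to first).

#' Signed polygon area by the shoelace formula
#'
#' Positive for counterclockwise vertex order.
#'
#' @param poly numeric matrix, n x 2, one vertex per row; closure implicit.
#' @return Signed area (mm^2 for mm coordinates).
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon centroid (area centroid)
#'
#' @inheritParams polygon_area
#' @return Length-2 numeric vector.
#' @export
polygon_centroid <- function(poly) {
  poly <- as.matrix(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100) return(colMeans(poly))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Cumulative arc length along a closed polygon
#'
#' @inheritParams polygon_area
#' @return Numeric vector of length n + 1: 0 at the first vertex, total
#'   perimeter at the closing edge.
#' @export
polygon_arclength <- function(poly) {
  poly <- as.matrix(poly)
  seg <- sqrt(rowSums((rbind(poly[-1, , drop = FALSE], poly[1, ]) - poly)^2))
  c(0, cumsum(seg))
}

#' Resample a closed polygon at uniform arc length
#'
#' @inheritParams polygon_area
#' @param n number of output vertices.
#' @param s0 arc-length offset of the first output vertex (mm).
#' @return n x 2 matrix.
#' @export
polygon_resample <- function(poly, n, s0 = 0) {
  poly <- as.matrix(poly)
  s <- polygon_arclength(poly)
  L <- s[length(s)]
  targets <- (s0 + L * (seq_len(n) - 1) / n) %% L
  px <- c(poly[, 1], poly[1, 1]); py <- c(poly[, 2], poly[1, 2])
  cbind(stats::approx(s, px, xout = targets)$y,
        stats::approx(s, py, xout = targets)$y)
}

#' Test whether points lie inside a closed polygon
#'
#' Even-odd ray casting.
#'
#' @param pts m x 2 matrix of query points.
#' @inheritParams polygon_area
#' @return Logical vector of length m.
#' @export
points_in_polygon <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  poly <- as.matrix(poly)
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- c(xs[-1], xs[1]); ye <- c(ys[-1], ys[1])
  vapply(seq_len(nrow(pts)), function(i) {
    x <- pts[i, 1]; y <- pts[i, 2]
    crosses <- ((ys > y) != (ye > y)) &
      (x < xs + (y - ys) * (xe - xs) / (ye - ys))
    sum(crosses) %% 2L == 1L
  }, logical(1))
}

#' Is a closed polygon simple (non-self-intersecting)?
#'
#' Brute-force segment pair check; adequate for the 64-256 vertex contours
#' this package works with.
#'
#' @inheritParams polygon_area
#' @return Logical scalar.
#' @export
polygon_is_simple <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  a <- poly
  b <- rbind(poly[-1, , drop = FALSE], poly[1, ])
  cross <- function(ox, oy, px, py, qx, qy) {
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    js <- seq(i + 2, jmax)
    p1 <- a[i, ]; p2 <- b[i, ]
    p3x <- a[js, 1]; p3y <- a[js, 2]; p4x <- b[js, 1]; p4y <- b[js, 2]
    d1 <- cross(p3x, p3y, p4x, p4y, p1[1], p1[2])
    d2 <- cross(p3x, p3y, p4x, p4y, p2[1], p2[2])
    d3 <- cross(p1[1], p1[2], p2[1], p2[2], p3x, p3y)
    d4 <- cross(p1[1], p1[2], p2[1], p2[2], p4x, p4y)
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

#' Minimum distance between two polygons (vertex-to-segment)
#'
#' @param p,q n x 2 vertex matrices of closed polygons.
#' @return Scalar distance (mm).
#' @export
polygon_min_distance <- function(p, q) {
  min(.min_pt_seg(p, q), .min_pt_seg(q, p))
}

.min_pt_seg <- function(pts, poly) {
  poly <- as.matrix(poly)
  a <- poly
  b <- rbind(poly[-1, , drop = FALSE], poly[1, ])
  dmin <- Inf
  for (i in seq_len(nrow(pts))) {
    px <- pts[i, 1]; py <- pts[i, 2]
    vx <- b[, 1] - a[, 1]; vy <- b[, 2] - a[, 2]
    wx <- px - a[, 1];     wy <- py - a[, 2]
    t <- pmin(pmax((wx * vx + wy * vy) / (vx^2 + vy^2), 0), 1)
    d2 <- (wx - t * vx)^2 + (wy - t * vy)^2
    dmin <- min(dmin, min(d2))
  }
  sqrt(dmin)
}

#' Interpolate values defined on polygon vertices at arc-length positions
#'
#' Periodic linear interpolation along the closed polyline.
#'
#' @param poly n x 2 closed polygon.
#' @param vals numeric vector (length n) or matrix (n x k) of vertex values.
#' @param s arc-length positions at which to interpolate.
#' @return Vector or matrix of interpolated values.
#' @keywords internal
polygon_interp <- function(poly, vals, s) {
  arc <- polygon_arclength(poly)
  L <- arc[length(arc)]
  s <- s %% L
  vals <- as.matrix(vals)
  valsc <- rbind(vals, vals[1, , drop = FALSE])
  out <- apply(valsc, 2, function(v) stats::approx(arc, v, xout = s)$y)
  if (ncol(vals) == 1) as.numeric(out) else out
}
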