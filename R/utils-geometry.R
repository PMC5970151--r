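# Low-level polyline / polygon helpers shared by every stage.

#' Round half away from zero
#'
#' Deterministic half-up rounding (base `round()` rounds half to even, which
#' would turn a 4.5-division panel into 4 diamonds instead of 5).
#' @param x numeric vector
#' @return integer-valued numeric vector
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

#' Clamp values to an interval
#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Cumulative arc length of a polyline
#'
#' @param pts numeric matrix, one point per row (2 or 3 columns)
#' @return numeric vector of length `nrow(pts)` starting at 0
#' @keywords internal
cum_arclength <- function(pts) {
  if (nrow(pts) < 2) return(0)
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(d))
}

#' Total length of a polyline
#' @keywords internal
polyline_length <- function(pts) {
  s <- cum_arclength(pts)
  s[length(s)]
}

#' Resample an open polyline to n points uniform in arc length
#'
#' Endpoints are preserved exactly.
#' @param pts point matrix (rows = points)
#' @param n number of output points (>= 2)
#' @keywords internal
resample_polyline <- function(pts, n) {
  stopifnot(nrow(pts) >= 2, n >= 2)
  s <- cum_arclength(pts)
  # collapse duplicate parameter values so approx() stays monotone
  keep <- c(TRUE, diff(s) > 1e-12)
  pts <- pts[keep, , drop = FALSE]
  s <- s[keep]
  if (nrow(pts) == 1) return(pts[rep(1, n), , drop = FALSE])
  ts <- seq(0, s[length(s)], length.out = n)
  out <- vapply(seq_len(ncol(pts)), function(j)
    stats::approx(s, pts[, j], xout = ts, rule = 2)$y,
    numeric(n))
  matrix(out, nrow = n)
}

#' Resample a closed loop to n points uniform in arc length
#'
#' The input loop need not repeat its first point; the output does not repeat
#' it either. Point 1 of the output coincides with point 1 of the input.
#' @keywords internal
resample_loop <- function(pts, n) {
  if (all(abs(pts[1, ] - pts[nrow(pts), ]) < 1e-12)) {
    pts <- pts[-nrow(pts), , drop = FALSE]
  }
  closed <- rbind(pts, pts[1, ])
  s <- cum_arclength(closed)
  total <- s[length(s)]
  keep <- c(TRUE, diff(s) > 1e-12)
  closed <- closed[keep, , drop = FALSE]
  s <- s[keep]
  ts <- seq(0, total, length.out = n + 1)[-(n + 1)]
  out <- vapply(seq_len(ncol(closed)), function(j)
    stats::approx(s, closed[, j], xout = ts, rule = 2)$y,
    numeric(n))
  matrix(out, nrow = n)
}

#' Periodic cubic spline through a closed sequence of points
#'
#' Interpolates each coordinate against cumulative chord length (the closing
#' chord included) with a periodic cubic spline and samples the curve densely.
#' This is the interpolation primitive used both for section repair and for
#' smoothing merged dual sections.
#'
#' @param pts matrix of control points (loop, first point not repeated)
#' @param n_out number of output samples
#' @return matrix `n_out` x ncol(pts); a closed loop (first point not repeated)
#' @keywords internal
periodic_spline_loop <- function(pts, n_out = 200) {
  m <- nrow(pts)
  stopifnot(m >= 3)
  closed <- rbind(pts, pts[1, ])
  s <- cum_arclength(closed)
  total <- s[length(s)]
  ts <- seq(0, total, length.out = n_out + 1)[-(n_out + 1)]
  out <- matrix(0, n_out, ncol(pts))
  for (j in seq_len(ncol(pts))) {
    y <- closed[, j]
    if (abs(y[1] - y[length(y)]) > 1e-9) y[length(y)] <- y[1]
    sp <- stats::spline(s, y, method = "periodic", xout = ts)
    out[, j] <- sp$y
  }
  out
}

#' Signed area of a 2D polygon (positive = counter-clockwise)
#' @keywords internal
polygon_area2d <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  i2 <- c(seq_len(nrow(pts))[-1], 1)
  sum(x * y[i2] - x[i2] * y) / 2
}

#' Centroid of a 2D polygon (area-weighted)
#' @keywords internal
polygon_centroid2d <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  i2 <- c(seq_len(nrow(pts))[-1], 1)
  cr <- x * y[i2] - x[i2] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(pts))
  c(sum((x + x[i2]) * cr), sum((y + y[i2]) * cr)) / (6 * a)
}

#' Do any two non-adjacent segments of a polyline intersect?
#'
#' Brute-force O(n^2) segment test; input polylines are short (clinician
#' curves, tens of points).
#' @param pts XY matrix
#' @param closed treat as closed loop
#' @keywords internal
polyline_self_intersects <- function(pts, closed = FALSE) {
  n <- nrow(pts)
  segs <- cbind(seq_len(n - 1), 2:n)
  if (closed) segs <- rbind(segs, c(n, 1))
  m <- nrow(segs)
  if (m < 3) return(FALSE)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      # skip segments sharing a vertex
      if (length(intersect(segs[i, ], segs[j, ])) > 0) next
      if (segments_intersect(pts[segs[i, 1], ], pts[segs[i, 2], ],
                             pts[segs[j, 1], ], pts[segs[j, 2], ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Proper 2D segment intersection test
#' @keywords internal
segments_intersect <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(v) < 1e-12) 0 else sign(v)
  }
  o1 <- orient(p1, p2, q1); o2 <- orient(p1, p2, q2)
  o3 <- orient(q1, q2, p1); o4 <- orient(q1, q2, p2)
  (o1 != o2) && (o3 != o4) && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0
}

#' Are all test points inside (or on) a polygon?
#' @keywords internal
points_in_polygon <- function(pts, poly) {
  r <- sp::point.in.polygon(pts[, 1], pts[, 2],
                            c(poly[, 1], poly[1, 1]), c(poly[, 2], poly[1, 2]))
  r > 0
}

#' Rotation matrix mapping unit vector a onto unit vector b
#' @keywords internal
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) {
    # 180 degrees: rotate about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * a) * a; ax <- ax / sqrt(sum(ax^2))
    return(2 * outer(ax, ax) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * (1 / (1 + cth))
}

#' Any orthonormal frame with given z-axis
#' @return 3x3 matrix with columns (x, y, z)
#' @keywords internal
frame_from_normal <- function(nrm) {
  z <- nrm / sqrt(sum(nrm^2))
  h <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  x <- h - sum(h * z) * z; x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3], z[1] * x[2] - z[2] * x[1])
  cbind(x, y, z)
}
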