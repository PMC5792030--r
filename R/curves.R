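# Low-level planar-curve primitives shared by the geometry and solver modules.

#' Signed and absolute polygon area (shoelace formula)
#'
#' Area of a simple polygon from its ordered vertices. The absolute value is
#' returned so the result does not depend on traversal orientation.
#'
#' @param vertices numeric matrix (or data frame) with two columns (x, y) and
#'   at least three rows, the polygon vertices in boundary order.
#' @return Area in squared input units (scalar).
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' @export
polygon_area <- function(vertices) {
  abs(shoelace_signed(vertices))
}

shoelace_signed <- function(vertices) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3L || ncol(v) != 2L) {
    stop("polygon needs at least 3 vertices with (x, y) columns", call. = FALSE)
  }
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  0.5 * sum(x * yn - xn * y)
}

# int y dx along an open polyline (trapezoid convention); frame-dependent,
# used consistently for all pieces of a closed boundary.
polyline_ydx <- function(xy) {
  n <- nrow(xy)
  sum((xy[-1L, 2L] + xy[-n, 2L]) / 2 * diff(xy[, 1L]))
}

# straight segment int y dx from p to q
segment_ydx <- function(p, q) (q[1L] - p[1L]) * (p[2L] + q[2L]) / 2

# trapezoid cumulative integral of node values v on an equispaced grid
trapz_cum <- function(v, ds) {
  n <- length(v)
  c(0, cumsum((v[-1L] + v[-n]) / 2 * ds))
}

rot90ccw <- function(v) c(-v[2L], v[1L])

# signed angle (radians, CCW positive) from vector u to vector w
signed_angle <- function(u, w) {
  atan2(w[2L], w[1L]) - atan2(u[2L], u[1L])
}

rotate_about <- function(p, centre, theta) {
  d <- p - centre
  centre + c(cos(theta) * d[1L] - sin(theta) * d[2L],
             sin(theta) * d[1L] + cos(theta) * d[2L])
}

## ---- parametric polynomial curves -------------------------------------

# Evaluate a power-basis polynomial with coefficient vector a (a[1] + a[2] t + ...)
poly_eval <- function(a, t) {
  out <- numeric(length(t))
  for (k in rev(seq_along(a))) out <- out * t + a[k]
  out
}

poly_deriv_coef <- function(a) {
  n <- length(a)
  if (n <= 1L) return(0)
  a[-1L] * seq_len(n - 1L)
}

#' Convert Bezier control points to power-basis polynomial coefficients
#'
#' A degree-n Bezier curve is a parametric polynomial in t over \[0, 1\]; this
#' returns the power-basis coefficients of its x(t) and y(t) components, the
#' form consumed by [reference_contour_from_polynomial()].
#'
#' @param control_points numeric matrix with columns (x, y); rows are the
#'   Bezier control points, first row = curve start, last row = curve end.
#' @return list with components `x` and `y`, each a coefficient vector
#'   (constant term first).
#' @export
bezier_to_poly <- function(control_points) {
  cp <- as.matrix(control_points)
  n <- nrow(cp) - 1L
  # power basis via iterated forward differences: B(t) = sum_k C(n,k) D^k P0 t^k
  coef <- matrix(0, n + 1L, 2L)
  d <- cp
  for (k in 0:n) {
    coef[k + 1L, ] <- choose(n, k) * d[1L, ]
    if (k < n) d <- diff(d)
  }
  list(x = coef[, 1L], y = coef[, 2L])
}

# Evaluate parametric curve (and derivative) given power-basis coeffs
poly_curve_eval <- function(coeffs, t) {
  cbind(poly_eval(coeffs$x, t), poly_eval(coeffs$y, t))
}
poly_curve_deriv <- function(coeffs, t) {
  cbind(poly_eval(poly_deriv_coef(coeffs$x), t),
        poly_eval(poly_deriv_coef(coeffs$y), t))
}

## ---- circular arc of the outer tunnel ---------------------------------

# The outer tunnel is a circular segment whose chord is the OHC (from apex a
# to base b) and whose arc (fixed length arc_len) bulges toward the abneural
# side, i.e. toward rot90ccw of the chord direction. phi is the angle between
# chord and arc at either endpoint (half the central angle).
arc_geometry <- function(a, b, arc_len, phi) {
  u <- b - a
  chord <- sqrt(sum(u^2))
  u <- u / chord
  n <- rot90ccw(u)
  R <- arc_len / (2 * phi)
  centre <- (a + b) / 2 - R * cos(phi) * n
  list(centre = centre, R = R, u = u, n = n)
}

# Polyline discretisation of the arc from a to b (passing through the bulge)
arc_polyline <- function(a, b, arc_len, phi, k = 720L) {
  g <- arc_geometry(a, b, arc_len, phi)
  th_a <- atan2(a[2L] - g$centre[2L], a[1L] - g$centre[1L])
  th_b <- atan2(b[2L] - g$centre[2L], b[1L] - g$centre[1L])
  th_n <- atan2(g$n[2L], g$n[1L])
  d1 <- (th_b - th_a) %% (2 * pi)
  dn <- (th_n - th_a) %% (2 * pi)
  if (dn > d1) d1 <- d1 - 2 * pi
  th <- th_a + seq(0, d1, length.out = k + 1L)
  cbind(g$centre[1L] + g$R * cos(th), g$centre[2L] + g$R * sin(th))
}

# Tangent angle of the arc at the apex endpoint a, in the traversal direction
# a -> b over the bulge (analytic: perpendicular to the radius, oriented by
# the traversal sense).
arc_tangent_at_apex <- function(a, b, arc_len, phi) {
  g <- arc_geometry(a, b, arc_len, phi)
  th_a <- atan2(a[2L] - g$centre[2L], a[1L] - g$centre[1L])
  th_b <- atan2(b[2L] - g$centre[2L], b[1L] - g$centre[1L])
  th_n <- atan2(g$n[2L], g$n[1L])
  d1 <- (th_b - th_a) %% (2 * pi)
  dn <- (th_n - th_a) %% (2 * pi)
  sgn <- if (dn > d1) -1 else 1
  th_a + sgn * pi / 2
}

# Signed radial clearance of points from the outer-tunnel circle, restricted
# to the arc's swept sector: positive = outside the circle. Points outside
# the sector return +Inf (the circle there is not part of the tunnel
# boundary).
arc_sector_clearance <- function(xy, a, b, arc_len, phi) {
  g <- arc_geometry(a, b, arc_len, phi)
  th_a <- atan2(a[2L] - g$centre[2L], a[1L] - g$centre[1L])
  th_b <- atan2(b[2L] - g$centre[2L], b[1L] - g$centre[1L])
  th_n <- atan2(g$n[2L], g$n[1L])
  d1 <- (th_b - th_a) %% (2 * pi)
  dn <- (th_n - th_a) %% (2 * pi)
  if (dn > d1) d1 <- d1 - 2 * pi
  th <- atan2(xy[, 2L] - g$centre[2L], xy[, 1L] - g$centre[1L])
  rel <- (th - th_a) %% (2 * pi)
  if (d1 < 0) rel <- rel - 2 * pi
  inside_sector <- if (d1 >= 0) rel <= d1 else rel >= d1
  r <- sqrt((xy[, 1L] - g$centre[1L])^2 + (xy[, 2L] - g$centre[2L])^2) - g$R
  r[!inside_sector] <- Inf
  r
}

# Minimal distance between two polylines (vertex-based; adequate for the
# densely sampled curves used in validation).
polyline_min_dist <- function(p, q) {
  min(apply(p, 1L, function(r) min(sqrt((q[, 1L] - r[1L])^2 + (q[, 2L] - r[2L])^2))))
}
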