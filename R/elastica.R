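# Constrained planar elastica for the Hensen-cell contour.
#
# The contour is parametrised by its tangent angle phi(s) at N + 1
# equispaced arc-length nodes. The solver finds a stationary point of the
# discrete Lagrangian
#
#   L(phi, lambda) = sum_i (ds/2) ((phi_{i+1}-phi_i)/ds
#                                  - Gamma_eps (phi0_{i+1}-phi0_i)/ds)^2
#     + lambda_x (x_N - x_e) + lambda_y (y_N - y_e)
#     + lambda_A (S[phi] - c_area)
#     + lambda_0 ((phi_1 - phi_0)/ds - Gamma_eps kappa_0(0))
#     + lambda_L (phi_N - phi_e)
#
# where node coordinates follow from trapezoid cumulative quadrature of
# (cos phi, sin phi), S[phi] is the discrete contour integral of y dx (the
# line-integral form of the enclosed-area constraint), the forward
# difference in the lambda_0 row is the printed first-order form of the
# natural boundary condition, and phi_e pins the angle between contour and
# outer-tunnel arc at the junction. The bending energy is measured against
# the uniformly stretched reference, Gamma_eps = 1 + eps * Gamma.

#' Discrete bending energy of the contour
#'
#' Energy of a deformed tangent-angle vector about the (uniformly
#' stretched) preferred shape:
#' `sum_i (ds/2) * ((phi[i+1]-phi[i])/ds - g_eps*(phi0[i+1]-phi0[i])/ds)^2`.
#' It is non-negative and vanishes iff every deformed increment equals the
#' `g_eps`-scaled reference increment.
#'
#' @param phi_nodes,phi0_nodes tangent angles of the deformed and reference
#'   contour at the N + 1 nodes (radians); equal length.
#' @param gamma_eps stretch factor Gamma_eps = 1 + epsilon * Gamma.
#' @param ds deformed node spacing (um, > 0).
#' @return scalar energy (1/um units of the discrete functional).
#' @export
discrete_curvature_energy <- function(phi_nodes, phi0_nodes, gamma_eps, ds) {
  if (length(phi_nodes) != length(phi0_nodes)) {
    stop("phi_nodes and phi0_nodes must have equal length", call. = FALSE)
  }
  if (ds <= 0) stop("ds must be positive", call. = FALSE)
  e <- (diff(phi_nodes) - gamma_eps * diff(phi0_nodes)) / ds
  sum(ds / 2 * e^2)
}

# Node coordinates (local frame, origin at the anchor) by trapezoid
# cumulative quadrature.
contour_coords <- function(phi, ds, origin = c(0, 0)) {
  cbind(origin[1L] + trapz_cum(cos(phi), ds),
        origin[2L] + trapz_cum(sin(phi), ds))
}

#' Enclosed-area constant for the Hensen contour
#'
#' The contour's discrete line integral of y dx must take the value that
#' keeps the total Hensen-cell region (bounded by the contour, the deformed
#' outer-tunnel arc from apex to base, the Deiters' line, and the basilar
#' membrane back to the anchor) at its reference area. Since the
#' non-contour pieces are known once the fluid space is solved, the
#' required constant is the reference total minus their line-integral
#' contributions.
#'
#' @param geometry an `oc_geometry`.
#' @param fluid_state a converged [solve_fluid_space()] result.
#' @param n_nodes contour discretisation (defaults to the geometry's).
#' @return the prescribed value of the contour's discrete `int y dx` (um^2).
#' @export
area_constant_for <- function(geometry, fluid_state, n_nodes = geometry$config$n_nodes) {
  tab <- contour_table(geometry, n_nodes)
  arc <- arc_polyline(fluid_state$ohc_apex, fluid_state$ohc_base,
                      geometry$a_arc, fluid_state$phi)
  S_other <- polyline_ydx(arc) +
    segment_ydx(fluid_state$ohc_base, geometry$dc_anchor) +
    segment_ydx(geometry$dc_anchor, tab$anchor)
  tab$S0 + tab$S_other0 - S_other
}

## ---- residual of the stationarity system ------------------------------

# z = (phi[0..N], lambda_x, lambda_y, lambda_A, lambda_0, lambda_L)
# xe, ye are the prescribed endpoint in the local (anchor-origin) frame;
# y_anchor is the anchor's global height so the area line integral int y dx
# is evaluated in the same global frame as the prescribed c_area.
elastica_residual <- function(z, N, ds, phi0v, gamma_eps, kappa0, xe, ye,
                              c_area, phi_e, y_anchor = 0) {
  phi <- z[1:(N + 1L)]
  lam <- z[(N + 2L):(N + 6L)]
  cphi <- cos(phi); sphi <- sin(phi)
  x <- trapz_cum(cphi, ds)
  y_loc <- trapz_cum(sphi, ds)
  y <- y_anchor + y_loc

  e <- (diff(phi) - gamma_eps * diff(phi0v)) / ds
  gE <- c(0, e) - c(e, 0)   # dE/dphi_k = e_{k-1} - e_k

  S <- sum((y[-1L] + y[-(N + 1L)]) / 2 * diff(x))

  # endpoint constraint gradients (trapezoid weights)
  w <- c(ds / 2, rep(ds, N - 1L), ds / 2)
  gCx <- -w * sphi
  gCy <-  w * cphi

  # area gradient: S depends on phi_k through all coordinates x_j, y_j with
  # j >= k; accumulate with suffix sums of dS/dx_j, dS/dy_j.
  dSdx <- c(-(y[1L] + y[2L]) / 2,
            (y[seq_len(N - 1L)] - y[3:(N + 1L)]) / 2,
            (y[N] + y[N + 1L]) / 2)
  dSdy <- c((x[2L] - x[1L]) / 2,
            (x[3:(N + 1L)] - x[seq_len(N - 1L)]) / 2,
            (x[N + 1L] - x[N]) / 2)
  sufx <- rev(cumsum(rev(dSdx)))
  sufy <- rev(cumsum(rev(dSdy)))
  Ak <- ds * (sufx - dSdx) + (ds / 2) * dSdx
  Bk <- ds * (sufy - dSdy) + (ds / 2) * dSdy
  Ak[1L] <- (ds / 2) * (sufx[1L] - dSdx[1L])
  Bk[1L] <- (ds / 2) * (sufy[1L] - dSdy[1L])
  gCA <- -sphi * Ak + cphi * Bk

  gB0 <- c(-1 / ds, 1 / ds, rep(0, N - 1L))
  gBL <- c(rep(0, N), 1)

  grad <- gE + lam[1L] * gCx + lam[2L] * gCy + lam[3L] * gCA +
    lam[4L] * gB0 + lam[5L] * gBL

  c(grad,
    x[N + 1L] - xe,
    y_loc[N + 1L] - ye,
    S - c_area,
    (phi[2L] - phi[1L]) / ds - gamma_eps * kappa0,
    phi[N + 1L] - phi_e)
}

# Damped Newton with finite-difference Jacobian on a general residual.
newton_fd <- function(z0, resfun, tol = 1e-9, max_iter = 60L) {
  z <- z0
  n <- length(z)
  r <- resfun(z)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < tol) {
      return(list(z = z, converged = TRUE, res = max(abs(r)), iters = it - 1L))
    }
    J <- matrix(0, n, n)
    h <- 1e-7 * pmax(1, abs(z))
    for (j in seq_len(n)) {
      zp <- z
      zp[j] <- zp[j] + h[j]
      J[, j] <- (resfun(zp) - r) / h[j]
    }
    dz <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(dz) || !all(is.finite(dz))) {
      return(list(z = z, converged = FALSE, res = max(abs(r)), iters = it))
    }
    lam <- 1
    repeat {
      zn <- z - lam * dz
      rn <- resfun(zn)
      if (all(is.finite(rn)) && (max(abs(rn)) < max(abs(r)) || lam <= 1 / 64)) break
      lam <- lam / 2
    }
    if (lam <= 1 / 64 && (!all(is.finite(rn)) || max(abs(rn)) >= max(abs(r)))) {
      return(list(z = z, converged = FALSE, res = max(abs(r)), iters = it))
    }
    z <- zn; r <- rn
  }
  list(z = z, converged = max(abs(r)) < tol, res = max(abs(r)), iters = max_iter)
}

# Project the raw reference tangent table onto the discrete constraint set
# (exact endpoint, end-angle and natural boundary rows; no area row) so the
# reference configuration is feasible with zero energy at eps = 0.
project_reference_contour <- function(raw, apex_offset) {
  N <- length(raw$phi) - 1L
  ds <- raw$L0 / N
  resfun <- function(z) {
    full <- elastica_residual(c(z[1:(N + 1L)], z[N + 2L], z[N + 3L], 0,
                                z[N + 4L], z[N + 5L]),
                              N, ds, raw$phi, 1, raw$kappa0_start,
                              apex_offset[1L], apex_offset[2L], 0,
                              raw$phi[N + 1L])
    full[-(N + 4L)]   # drop the area row
  }
  st <- newton_fd(c(raw$phi, 0, 0, 0, 0), resfun, tol = 1e-11)
  if (!st$converged) {
    stop("reference-contour projection failed to converge", call. = FALSE)
  }
  list(phi = st$z[1:(N + 1L)])
}

#' Solve the constrained Hensen-contour elastica
#'
#' Given a converged fluid-space state, finds the tangent-angle vector and
#' Lagrange multipliers at which the discrete Lagrangian is stationary: the
#' contour of length `(1 + epsilon * Gamma) * L_HC0` that minimises bending
#' energy about the uniformly stretched reference shape subject to the
#' endpoint landing on the deformed OHC apex, conservation of the enclosed
#' Hensen area, the first-order natural boundary condition at the anchor,
#' and a fixed contour-arc junction angle at the apex.
#'
#' @inheritParams area_constant_for
#' @param epsilon,gamma contraction and Hensen-contour extensibility.
#' @param control solver settings ([oc_control()]); `n_nodes` overrides the
#'   geometry default (must be >= 50).
#' @param init optional initial unknown vector (previous continuation step).
#' @return An object of class `oc_hensen_contour` with fields `phi_nodes`,
#'   `arc_length`, `ds`, `gamma_eps`, `multipliers`, `coords` (global
#'   frame), `energy`, `residual`, `iters`.
#' @export
solve_hensen_contour <- function(geometry, fluid_state, epsilon, gamma,
                                 control = oc_control(), init = NULL) {
  n_nodes <- if (!is.null(control$n_nodes)) control$n_nodes else geometry$config$n_nodes
  if (n_nodes < 50L) stop("elastica needs n_nodes >= 50", call. = FALSE)
  tab <- contour_table(geometry, n_nodes)
  N <- tab$N
  gamma_eps <- 1 + epsilon * gamma
  ds <- gamma_eps * tab$ds0

  xe <- fluid_state$ohc_apex[1L] - tab$anchor[1L]
  ye <- fluid_state$ohc_apex[2L] - tab$anchor[2L]
  c_area <- area_constant_for(geometry, fluid_state, n_nodes)
  phi_e <- arc_tangent_at_apex(fluid_state$ohc_apex, fluid_state$ohc_base,
                               geometry$a_arc, fluid_state$phi) + tab$phie_off

  z0 <- if (!is.null(init)) init else c(tab$phi0, 0, 0, 0, 0, 0)
  st <- newton_fd(z0, function(z) {
    elastica_residual(z, N, ds, tab$phi0, gamma_eps, tab$kappa0_start,
                      xe, ye, c_area, phi_e, y_anchor = tab$anchor[2L])
  }, tol = control$tol, max_iter = control$max_iter)

  if (!st$converged) {
    stop(structure(class = c("oc_solver_error", "error", "condition"),
                   list(message = sprintf(
                     paste0("Hensen elastica did not converge at epsilon = %.5g, ",
                            "Gamma = %.3g (max residual %.3g); the area/length ",
                            "constraints admit no nearby solution"),
                     epsilon, gamma, st$res),
                     call = NULL, residual = st$res, epsilon = epsilon)))
  }

  phi <- unname(st$z[1:(N + 1L)])
  structure(list(
    phi_nodes = phi,
    phi0_nodes = tab$phi0,
    arc_length = gamma_eps * tab$L0,
    ds = ds, gamma_eps = gamma_eps, n_nodes = N,
    multipliers = setNames(st$z[(N + 2L):(N + 6L)],
                           c("lambda_x", "lambda_y", "lambda_A",
                             "lambda_s0", "lambda_sL")),
    coords = contour_coords(phi, ds, tab$anchor),
    energy = discrete_curvature_energy(phi, tab$phi0, gamma_eps, ds),
    c_area = c_area, phi_e = phi_e,
    epsilon = epsilon, gamma = gamma,
    residual = st$res, iters = st$iters,
    anchor = tab$anchor, L0 = tab$L0
  ), class = "oc_hensen_contour")
}

#' Position of a material point on the (deformed) contour
#'
#' The contour stretches uniformly, so the material point at reference arc
#' length `s0` sits at deformed arc length `gamma_eps * s0`; its position is
#' linearly interpolated between nodes.
#'
#' @param contour an `oc_hensen_contour` (or a reference table from the
#'   geometry cache).
#' @param s0_reference reference arc length, 0 <= s0 <= L_HC0 (um).
#' @return point (x, y) in the global frame (um).
#' @export
material_point <- function(contour, s0_reference) {
  if (s0_reference < 0 || s0_reference > contour$L0 * (1 + 1e-12)) {
    stop("s0_reference outside [0, L_HC0]", call. = FALSE)
  }
  idx <- contour$gamma_eps * s0_reference / contour$ds
  i <- min(max(floor(idx), 0), contour$n_nodes - 1L)
  fr <- idx - i
  contour$coords[i + 1L, ] * (1 - fr) + contour$coords[i + 2L, ] * fr
}

# Reference position of a material point (same interpolation on the
# reference table).
reference_point <- function(geometry, s0_reference, n_nodes = geometry$config$n_nodes) {
  tab <- contour_table(geometry, n_nodes)
  idx <- s0_reference / tab$ds0
  i <- min(max(floor(idx), 0), tab$N - 1L)
  fr <- idx - i
  tab$xy0[i + 1L, ] * (1 - fr) + tab$xy0[i + 2L, ] * fr
}

#' @export
print.oc_hensen_contour <- function(x, ...) {
  cat(sprintf("<oc_hensen_contour> %d nodes, L = %.3f um (Gamma_eps %.6f)\n",
              x$n_nodes + 1L, x$arc_length, x$gamma_eps))
  cat(sprintf("  energy %.3e, max residual %.2e, %d Newton iterations\n",
              x$energy, x$residual, x$iters))
  invisible(x)
}
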