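# Area-conserving deformation of the fluid space (tunnel of Corti, space of
# Nuel, outer tunnel).
#
# The outer tunnel is a circular segment whose chord is the OHC and whose
# arc length a is fixed; its opening angle phi follows the contraction
# through sin(phi)/phi = (1 - eps) sin(phi0)/phi0. The deformed OHC
# endpoints (a_eps, b_eps) then solve a 4x4 nonlinear system: three length
# constraints (rigid reticular lamina, contracted OHC, extended Deiters'
# cell) plus conservation of A_SN + A_OT. The tunnel of Corti is rigid and
# cancels from the balance.

#' Chord length of a circular segment
#'
#' @param arc_length arc length of the segment (um).
#' @param phi angle between chord and arc at the endpoints, radians,
#'   in (0, pi).
#' @return chord length `arc_length * sin(phi) / phi` (um).
#' @export
chord_length <- function(arc_length, phi) {
  check_phi(phi)
  arc_length * sin(phi) / phi
}

#' Area of a circular segment (outer tunnel)
#'
#' @inheritParams chord_length
#' @return segment area `arc_length^2 * (1/(4 phi) - sin(2 phi)/(8 phi^2))`
#'   (um^2).
#' @export
outer_tunnel_area <- function(arc_length, phi) {
  check_phi(phi)
  arc_length^2 * (1 / (4 * phi) - sin(2 * phi) / (8 * phi^2))
}

check_phi <- function(phi) {
  if (any(!(phi > 0 & phi < pi))) {
    stop("outer-tunnel angle phi must lie in (0, pi)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Deformed outer-tunnel angle
#'
#' Solves `sin(phi)/phi = (1 - epsilon) * sin(phi0)/phi0` for the unique
#' root in (0, pi). Contraction (epsilon > 0) shortens the chord at fixed
#' arc length, so the angle opens; the map is strictly increasing in
#' epsilon.
#'
#' @param epsilon OHC contraction (dimensionless, positive = shortening).
#' @param phi0 reference angle, radians, in (0, pi).
#' @return deformed angle phi(epsilon), radians.
#' @export
deformed_tunnel_angle <- function(epsilon, phi0) {
  check_phi(phi0)
  rhs <- (1 - epsilon) * sin(phi0) / phi0
  if (rhs >= 1) {
    stop("no outer-tunnel solution: required chord exceeds the arc length ",
         "(sin(phi)/phi >= 1)", call. = FALSE)
  }
  lo <- 1e-12
  if (rhs <= sin(pi - lo) / pi) {
    stop("no outer-tunnel solution: required chord below the attainable range",
         call. = FALSE)
  }
  if (epsilon == 0) return(phi0)
  uniroot(function(p) sin(p) / p - rhs, c(lo, pi - lo), tol = 1e-14)$root
}

#' Solver settings for the deformation solvers
#'
#' @param tol residual tolerance (relative, max-norm) for the fluid-space
#'   and elastica Newton iterations.
#' @param max_iter maximum Newton iterations per continuation step.
#' @param continuation_step contraction step used for continuation from
#'   epsilon = 0 to the target.
#' @param n_nodes number of elastica elements (contour carries
#'   `n_nodes + 1` tangent-angle unknowns).
#' @return a list of class `oc_control`.
#' @export
oc_control <- function(tol = 1e-9, max_iter = 200L, continuation_step = 1e-3,
                       n_nodes = NULL) {
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 continuation_step = continuation_step,
                 n_nodes = if (!is.null(n_nodes)) as.integer(n_nodes)),
            class = "oc_control")
}

check_params <- function(epsilon, delta, gamma) {
  if (abs(epsilon) > 0.05) {
    stop("contraction |epsilon| capped at 0.05 (physiological |epsilon| <~ 0.02)",
         call. = FALSE)
  }
  if (delta < 0) stop("Deiters' extensibility Delta must be >= 0", call. = FALSE)
  if (gamma < 0) stop("Hensen extensibility Gamma must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Solve the area-conserving fluid-space deformation
#'
#' Finds the deformed OHC endpoints for a contraction `epsilon` and Deiters'
#' extensibility `delta` by Newton iteration with analytic Jacobian,
#' continuing in epsilon from the reference configuration. The solution
#' branch continuously connected to the reference is returned; residuals are
#' scaled by the reference lengths and areas.
#'
#' @param geometry an `oc_geometry`.
#' @param epsilon OHC contraction (positive = shortening), |epsilon| <= 0.05.
#' @param delta Deiters'-cell extensibility (dimensionless, >= 0).
#' @param control solver settings, see [oc_control()].
#' @return An object of class `oc_fluid_state`: deformed apex `ohc_apex` and
#'   base `ohc_base`, angle `phi`, areas `A_OT`, `A_SN`, `A_TC`, scaled
#'   constraint `residuals`, and a continuation log.
#' @export
solve_fluid_space <- function(geometry, epsilon, delta, control = oc_control()) {
  check_params(epsilon, delta, 0)
  n_step <- max(1L, ceiling(abs(epsilon) / control$continuation_step))
  eps_path <- seq(0, epsilon, length.out = n_step + 1L)[-1L]
  z <- c(geometry$ohc_apex_0, geometry$ohc_base_0)
  log <- list()
  if (length(eps_path) > 0) {
    for (e in eps_path) {
      st <- fluid_newton(geometry, e, delta, z, control)
      if (!st$converged) {
        stop(structure(class = c("oc_solver_error", "error", "condition"),
                       list(message = sprintf(
                         paste0("fluid-space solve did not converge at epsilon = %.5g ",
                                "(max scaled residual %.3g); no solution on the ",
                                "reference-connected branch"), e, st$res),
                         call = NULL, residuals = st$residuals, epsilon = e)))
      }
      z <- st$z
      log[[length(log) + 1L]] <- c(eps = e, iters = st$iters, res = st$res)
    }
  } else {
    st <- list(residuals = numeric(4L), res = 0, iters = 0L)
  }
  a <- z[1:2]; b <- z[3:4]
  phi <- deformed_tunnel_angle(epsilon, geometry$phi0)
  structure(list(
    ohc_apex = a, ohc_base = b, phi = phi,
    A_OT = outer_tunnel_area(geometry$a_arc, phi),
    A_SN = polygon_area(nuel_polygon(geometry, a, b)),
    A_TC = geometry$A_TC,
    epsilon = epsilon, delta = delta,
    residuals = st$residuals,
    log = do.call(rbind, log)
  ), class = "oc_fluid_state")
}

# One Newton solve of the 4x4 system at fixed epsilon, from initial guess z.
fluid_newton <- function(geometry, epsilon, delta, z, control) {
  g <- geometry
  phi <- tryCatch(deformed_tunnel_angle(epsilon, g$phi0), error = function(e) NULL)
  if (is.null(phi)) return(list(converged = FALSE, z = z, res = Inf, residuals = rep(Inf, 4L)))
  L_rl2 <- g$L_RL^2
  L_ohc <- (1 - epsilon) * g$L_OHC0
  L_dc <- (1 + epsilon * delta) * g$L_DC0
  S0 <- shoelace_signed(nuel_polygon(g, g$ohc_apex_0, g$ohc_base_0))
  target <- sign(S0) * (abs(S0) + g$A_OT0 - outer_tunnel_area(g$a_arc, phi))
  scale <- c(L_rl2, L_ohc^2, L_dc^2, abs(S0))

  resid <- function(z) {
    a <- z[1:2]; b <- z[3:4]
    c(sum((a - g$pivot_rl)^2) - L_rl2,
      sum((a - b)^2) - L_ohc^2,
      sum((b - g$dc_anchor)^2) - L_dc^2,
      shoelace_signed(nuel_polygon(g, a, b)) - target) / scale
  }
  # shoelace gradients for the splice order (pivot, a, b, dc, op)
  area_grad <- function(a, b) {
    dSa <- 0.5 * c(b[2L] - g$pivot_rl[2L], g$pivot_rl[1L] - b[1L])
    dSb <- 0.5 * c(g$dc_anchor[2L] - a[2L], a[1L] - g$dc_anchor[1L])
    c(dSa, dSb)
  }
  r <- resid(z)
  for (it in seq_len(control$max_iter)) {
    if (max(abs(r)) < control$tol) {
      return(list(converged = TRUE, z = z, res = max(abs(r)),
                  residuals = r, iters = it - 1L))
    }
    a <- z[1:2]; b <- z[3:4]
    J <- rbind(c(2 * (a - g$pivot_rl), 0, 0),
               c(2 * (a - b), -2 * (a - b)),
               c(0, 0, 2 * (b - g$dc_anchor)),
               area_grad(a, b)) / scale
    dz <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(dz) || !all(is.finite(dz))) {
      return(list(converged = FALSE, z = z, res = max(abs(r)), residuals = r, iters = it))
    }
    # damped update
    lam <- 1
    repeat {
      zn <- z - lam * dz
      rn <- resid(zn)
      if (all(is.finite(rn)) && (max(abs(rn)) < max(abs(r)) || lam <= 1 / 64)) break
      lam <- lam / 2
    }
    if (lam <= 1 / 64 && max(abs(rn)) >= max(abs(r))) {
      return(list(converged = FALSE, z = z, res = max(abs(r)), residuals = r, iters = it))
    }
    z <- zn; r <- rn
  }
  list(converged = max(abs(r)) < control$tol, z = z, res = max(abs(r)),
       residuals = r, iters = control$max_iter)
}

#' @export
print.oc_fluid_state <- function(x, ...) {
  cat(sprintf("<oc_fluid_state> epsilon %.4g, Delta %.3f\n", x$epsilon, x$delta))
  cat(sprintf("  apex (%.4f, %.4f)  base (%.4f, %.4f)  phi %.5f rad\n",
              x$ohc_apex[1], x$ohc_apex[2], x$ohc_base[1], x$ohc_base[2], x$phi))
  cat(sprintf("  A_SN %.3f  A_OT %.3f  max scaled residual %.2e\n",
              x$A_SN, x$A_OT, max(abs(x$residuals))))
  invisible(x)
}
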