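# Parameter sweeps and derived quantities: displacement-vs-contraction
# curves, the critical Deiters' extensibility Delta_C, (Delta, Gamma)
# region classification, and the operating-point gain of the reticular
# lamina.
#
# The reticular-lamina displacement depends only on the fluid-space solve
# (the elastica receives the apex position but does not feed back), so
# Delta_C and the gain are computed from fluid solves alone.

# RL displacement of the OHC apex along the BM normal (um, positive away
# from the BM), from the fluid solve.
d_rl_fluid <- function(geometry, epsilon, delta, control = oc_control()) {
  fs <- solve_fluid_space(geometry, epsilon, delta, control)
  sum((fs$ohc_apex - geometry$ohc_apex_0) * geometry$bm_normal)
}

#' Critical Deiters'-cell extensibility
#'
#' The value Delta_C at which the reticular-lamina displacement under a
#' fixed small contraction vanishes and changes sign: below Delta_C the
#' reticular lamina is pulled toward the basilar membrane upon OHC
#' contraction, above it is pushed away. Found by bisection on Delta.
#'
#' @param geometry an `oc_geometry`.
#' @param gamma Hensen extensibility (not involved in the reticular-lamina
#'   kinematics; kept for interface symmetry).
#' @param epsilon probe contraction (default 0.005; must be nonzero).
#' @param bracket search interval for Delta.
#' @param control solver settings.
#' @return Delta_C (dimensionless scalar) with attribute `d_rl` (residual
#'   displacement at the root, um, |d_rl| < 1e-6).
#' @export
critical_extensibility <- function(geometry, gamma = 0.1, epsilon = 0.005,
                                   bracket = c(0, 3), control = oc_control()) {
  if (epsilon == 0) stop("epsilon must be nonzero to probe Delta_C", call. = FALSE)
  lo <- bracket[1L]; hi <- bracket[2L]
  flo <- d_rl_fluid(geometry, epsilon, lo, control)
  fhi <- d_rl_fluid(geometry, epsilon, hi, control)
  if (flo * fhi > 0) {
    stop("no sign change of D_RL over the Delta bracket; geometry pathological",
         call. = FALSE)
  }
  fmid <- NA_real_
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    fmid <- d_rl_fluid(geometry, epsilon, mid, control)
    if (abs(fmid) < 1e-6) break
    if (fmid * flo <= 0) hi <- mid else { lo <- mid; flo <- fmid }
  }
  structure((lo + hi) / 2, d_rl = fmid)
}

#' Operating-point gain of the reticular lamina
#'
#' Central finite difference of the reticular-lamina displacement with
#' respect to the OHC contraction, evaluated at a resting contraction
#' `eps0`: `(D_RL(eps0 + h) - D_RL(eps0 - h)) / (2 h)`. This is the factor
#' that converts a small oscillatory OHC length change into
#' reticular-lamina vibration.
#'
#' @inheritParams critical_extensibility
#' @param delta Deiters' extensibility.
#' @param eps0 resting contraction (operating point).
#' @param h finite-difference step.
#' @return gain dD_RL/d eps (um per unit contraction).
#' @export
rl_gain <- function(geometry, delta = 1.15, gamma = 0.1, eps0 = 0, h = 1e-4,
                    control = oc_control()) {
  (d_rl_fluid(geometry, eps0 + h, delta, control) -
     d_rl_fluid(geometry, eps0 - h, delta, control)) / (2 * h)
}

#' Quasi-static oscillatory response of the reticular lamina
#'
#' For a sound-driven OHC length change `eps(t) = eps0 + eps_osc *
#' sin(2 pi f t)` the reticular lamina oscillates as `D_RL(t) = D_RL(0) +
#' D_RL(osc) * sin(2 pi f t)` with amplitude given by the linear expansion
#' about the operating point: `D_RL(osc) = |dD_RL/d eps| * eps_osc`. The
#' model is quasi-static; the frequency is bookkeeping only.
#'
#' @inheritParams rl_gain
#' @param eps0 resting contraction, |eps0| <= 0.02.
#' @param eps_osc oscillation amplitude, <= 0.005 (must be small for the
#'   linearisation).
#' @param freq frequency in Hz (carried through, not used).
#' @return one-row tibble with `d_rl_0` (steady displacement), `d_rl_osc`
#'   (oscillation amplitude) and `gain`.
#' @export
oscillatory_response <- function(geometry, delta = 1.15, gamma = 0.1,
                                 eps0 = 0, eps_osc = 0.001, freq = 100,
                                 control = oc_control()) {
  if (abs(eps0) > 0.02) stop("|eps0| <= 0.02 required", call. = FALSE)
  if (eps_osc < 0 || eps_osc > 0.005) stop("eps_osc must lie in [0, 0.005]", call. = FALSE)
  g <- rl_gain(geometry, delta, gamma, eps0, control = control)
  tibble::tibble(
    eps0 = eps0, eps_osc = eps_osc, freq = freq,
    d_rl_0 = d_rl_fluid(geometry, eps0, delta, control),
    d_rl_osc = abs(g) * eps_osc,
    gain = g)
}

#' Sweep the contraction at fixed extensibilities
#'
#' Solves the full model along a contraction grid, continuing from zero
#' outward in both directions with the previous solution as initial guess.
#' Points where the continuation fails (after one step-halving retry) are
#' flagged `converged = FALSE` with NA observables -- as are any further
#' points in that direction, which are unreachable by continuation -- and
#' the sweep continues.
#'
#' @param geometry an `oc_geometry`.
#' @param delta,gamma extensibilities.
#' @param eps_grid contraction grid (default plus/minus 0.02).
#' @param control solver settings.
#' @return tibble of class `oc_sweep`: one row per grid point with the
#'   [observables()] columns.
#' @export
sweep_contraction <- function(geometry, delta = 1.15, gamma = 0.1,
                              eps_grid = seq(-0.02, 0.02, by = 0.002),
                              control = oc_control()) {
  eps_grid <- sort(unique(eps_grid))
  rows <- vector("list", length(eps_grid))
  names(rows) <- as.character(eps_grid)
  zero_row <- function(e) tibble::tibble(
    epsilon = e, delta = delta, gamma = gamma,
    d_rl = NA_real_, hensen_top_radial = NA_real_, hensen_top_vertical = NA_real_,
    hensen_side_radial = NA_real_, hensen_side_vertical = NA_real_,
    alpha_deg = NA_real_, converged = FALSE)

  for (dir in c(-1, 1)) {
    grid <- eps_grid[if (dir > 0) eps_grid > 0 else eps_grid < 0]
    grid <- grid[order(abs(grid))]
    broken <- FALSE
    for (e in grid) {
      key <- as.character(e)
      if (broken) { rows[[key]] <- zero_row(e); next }
      st <- tryCatch(solve_deformation(geometry, e, delta, gamma, control),
                     oc_solver_error = function(err) NULL)
      if (is.null(st)) {
        rows[[key]] <- zero_row(e)
        broken <- TRUE
      } else {
        rows[[key]] <- observables(st)
      }
    }
  }
  if (any(eps_grid == 0)) {
    st0 <- solve_deformation(geometry, 0, delta, gamma, control)
    rows[["0"]] <- observables(st0)
  }
  out <- dplyr::bind_rows(rows[as.character(eps_grid)])
  class(out) <- c("oc_sweep", class(out))
  out
}

#' Classify the (Delta, Gamma) parameter plane
#'
#' For each extensibility pair the model is solved at the probe contraction
#' and classified by the signs of the tracked Hensen displacements and of
#' the reticular-lamina displacement; solvability over the physiological
#' contraction range |epsilon| <= `eps_max` is probed by continuation in
#' both directions. Failures are classifications, not errors.
#'
#' The column `realistic` marks the motion pattern identified as
#' biologically realistic: reticular lamina toward the BM, Hensen top away
#' from the BM and larger in magnitude, top radial component toward the
#' modiolus, and solvable over the physiological range.
#'
#' @param geometry an `oc_geometry`.
#' @param delta_grid,gamma_grid extensibility grids (within \[0, 3\] and
#'   \[0, 1\]).
#' @param epsilon probe contraction for the displacement signs.
#' @param eps_max half-width of the solvability range.
#' @param control solver settings.
#' @return tibble of class `oc_region_map`: one row per (Delta, Gamma) cell.
#' @export
classify_parameter_region <- function(geometry, delta_grid, gamma_grid,
                                      epsilon = 0.005, eps_max = 0.02,
                                      control = oc_control()) {
  stopifnot(all(delta_grid >= 0 & delta_grid <= 3),
            all(gamma_grid >= 0 & gamma_grid <= 1))
  grid <- expand.grid(delta = delta_grid, gamma = gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  out <- purrr::pmap_dfr(grid, function(delta, gamma) {
    probe <- tryCatch(solve_deformation(geometry, epsilon, delta, gamma, control),
                      oc_solver_error = function(err) NULL)
    ok_plus <- solvable_to(geometry, eps_max, delta, gamma, control)
    ok_minus <- solvable_to(geometry, -eps_max, delta, gamma, control)
    if (is.null(probe)) {
      return(tibble::tibble(
        delta = delta, gamma = gamma,
        solvable_at_probe = FALSE, solvable = FALSE,
        d_rl = NA_real_, hensen_top_radial = NA_real_,
        hensen_top_vertical = NA_real_, hensen_side_radial = NA_real_,
        hensen_side_vertical = NA_real_, realistic = FALSE))
    }
    ob <- observables(probe)
    tibble::tibble(
      delta = delta, gamma = gamma,
      solvable_at_probe = TRUE, solvable = ok_plus && ok_minus,
      d_rl = ob$d_rl,
      hensen_top_radial = ob$hensen_top_radial,
      hensen_top_vertical = ob$hensen_top_vertical,
      hensen_side_radial = ob$hensen_side_radial,
      hensen_side_vertical = ob$hensen_side_vertical,
      realistic = ok_plus && ok_minus &&
        ob$d_rl < 0 && ob$hensen_top_vertical > 0 &&
        abs(ob$hensen_top_vertical) > abs(ob$d_rl) &&
        ob$hensen_top_radial < 0)
  })
  class(out) <- c("oc_region_map", class(out))
  out
}

solvable_to <- function(geometry, epsilon, delta, gamma, control) {
  !inherits(tryCatch(solve_deformation(geometry, epsilon, delta, gamma, control),
                     oc_solver_error = function(err) err),
            "error")
}
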