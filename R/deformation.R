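# Composition of the fluid-space and elastica solves into one deformed
# state, and the observables reported relative to the fixed basilar
# membrane.

#' Solve the full organ-of-Corti deformation
#'
#' Continues from the reference configuration to the target contraction in
#' steps (previous solution as initial guess), solving the fluid space and
#' the Hensen elastica at each step. If the continuation fails it is
#' retried once with half the step; a persistent failure is reported as a
#' structured non-convergence (class `oc_solver_error`), never as a silent
#' partial state.
#'
#' @param geometry an `oc_geometry`.
#' @param epsilon OHC contraction (positive = shortening), |epsilon| <= 0.05.
#' @param delta Deiters'-cell extensibility (>= 0).
#' @param gamma Hensen-contour extensibility (>= 0).
#' @param control solver settings, see [oc_control()].
#' @return An object of class `oc_deformation`: `params`, `fluid`
#'   (`oc_fluid_state`), `contour` (`oc_hensen_contour`), `converged`,
#'   `geometry`, and a continuation `log` tibble.
#' @examples
#' \donttest{
#' geom <- default_geometry()
#' st <- solve_deformation(geom, epsilon = 0.005, delta = 1.15, gamma = 0.1)
#' observables(st)
#' }
#' @export
solve_deformation <- function(geometry, epsilon, delta, gamma,
                              control = oc_control()) {
  check_params(epsilon, delta, gamma)
  out <- try_continuation(geometry, epsilon, delta, gamma, control,
                          control$continuation_step)
  if (!is.null(out$error)) {
    half <- try_continuation(geometry, epsilon, delta, gamma, control,
                             control$continuation_step / 2)
    if (is.null(half$error)) {
      out <- half
    } else {
      stop(structure(class = c("oc_solver_error", "error", "condition"),
                     list(message = paste0(
                       "deformation unsolvable (continuation failed and persisted ",
                       "under one step-halving retry): ", conditionMessage(half$error)),
                       call = NULL, stage = half$stage, epsilon = epsilon,
                       delta = delta, gamma = gamma)))
    }
  }
  st <- structure(list(
    params = list(epsilon = epsilon, delta = delta, gamma = gamma,
                  control = control),
    fluid = out$fluid, contour = out$contour,
    converged = TRUE,
    residuals = c(fluid = max(abs(out$fluid$residuals)),
                  elastica = out$contour$residual),
    log = out$log,
    geometry = geometry
  ), class = "oc_deformation")
  # shared-apex consistency between the two solves
  gap <- sqrt(sum((st$contour$coords[st$contour$n_nodes + 1L, ] -
                     st$fluid$ohc_apex)^2))
  stopifnot(gap < 1e-6)
  solver_log(st)
  st
}

try_continuation <- function(geometry, epsilon, delta, gamma, control, step) {
  n_step <- max(1L, ceiling(abs(epsilon) / step))
  eps_path <- seq(0, epsilon, length.out = n_step + 1L)[-1L]
  zf <- c(geometry$ohc_apex_0, geometry$ohc_base_0)
  ze <- NULL
  fluid <- NULL; contour <- NULL
  log <- vector("list", length(eps_path))
  for (k in seq_along(eps_path)) {
    e <- eps_path[k]
    stf <- fluid_newton(geometry, e, delta, zf, control)
    if (!stf$converged) {
      return(list(error = simpleError(sprintf(
        "fluid stage failed at epsilon = %.5g (residual %.3g)", e, stf$res)),
        stage = "fluid"))
    }
    zf <- stf$z
    fluid <- fluid_state_from(geometry, e, delta, stf)
    contour <- tryCatch(
      solve_hensen_contour(geometry, fluid, e, gamma, control, init = ze),
      oc_solver_error = function(err) err)
    if (inherits(contour, "error")) {
      return(list(error = contour, stage = "elastica"))
    }
    ze <- c(contour$phi_nodes, contour$multipliers)
    log[[k]] <- tibble::tibble(
      epsilon = e, delta = delta, gamma = gamma,
      fluid_res = stf$res, fluid_iters = stf$iters,
      elastica_res = contour$residual, elastica_iters = contour$iters)
  }
  list(error = NULL, fluid = fluid, contour = contour,
       log = dplyr::bind_rows(log))
}

fluid_state_from <- function(geometry, epsilon, delta, stf) {
  a <- stf$z[1:2]; b <- stf$z[3:4]
  phi <- deformed_tunnel_angle(epsilon, geometry$phi0)
  structure(list(
    ohc_apex = a, ohc_base = b, phi = phi,
    A_OT = outer_tunnel_area(geometry$a_arc, phi),
    A_SN = polygon_area(nuel_polygon(geometry, a, b)),
    A_TC = geometry$A_TC,
    epsilon = epsilon, delta = delta,
    residuals = stf$residuals, log = NULL
  ), class = "oc_fluid_state")
}

solver_log <- function(st) {
  if (isTRUE(getOption("cortikin.verbose", FALSE))) {
    p <- st$params
    message(sprintf(
      "cortikin solve: eps=%+.5g Delta=%.3f Gamma=%.3f | fluid res %.2e | elastica res %.2e (%d steps)",
      p$epsilon, p$delta, p$gamma, st$residuals[["fluid"]],
      st$residuals[["elastica"]], nrow(st$log)))
  }
  invisible(st)
}

#' Observables of a deformed state
#'
#' Displacements are reported in the basilar-membrane frame ("radial" =
#' along the BM toward the stria vascularis, "vertical" = along the BM
#' normal toward scala vestibuli, i.e. away from the BM):
#' * `d_rl` -- reticular-lamina displacement of the OHC apex along the BM
#'   normal (um, positive away from the BM);
#' * `hensen_top_*`, `hensen_side_*` -- displacement components of the two
#'   tracked material points on the Hensen contour (um);
#' * `alpha_deg` -- OHC somatic rotation of the base about the apex
#'   relative to the reference orientation (degrees, positive =
#'   counter-clockwise).
#'
#' @param state an `oc_deformation`.
#' @param tracked_points named reference arc-length fractions of the tracked
#'   contour points (defaults to the geometry's `top` / `side`).
#' @return a one-row tibble, also carrying epsilon, Delta, Gamma.
#' @export
observables <- function(state, tracked_points = NULL) {
  geom <- state$geometry
  if (is.null(tracked_points)) {
    tracked_points <- unlist(geom$tracked_fractions)
  }
  n_nodes <- state$contour$n_nodes
  d_rl <- sum((state$fluid$ohc_apex - geom$ohc_apex_0) * geom$bm_normal)
  disp <- lapply(tracked_points, function(fr) {
    s0 <- fr * state$contour$L0
    d <- material_point(state$contour, s0) - reference_point(geom, s0, n_nodes)
    c(radial = sum(d * geom$bm_axis), vertical = sum(d * geom$bm_normal))
  })
  alpha <- signed_angle(geom$ohc_base_0 - geom$ohc_apex_0,
                        state$fluid$ohc_base - state$fluid$ohc_apex) * 180 / pi
  tibble::tibble(
    epsilon = state$params$epsilon,
    delta = state$params$delta,
    gamma = state$params$gamma,
    d_rl = d_rl,
    hensen_top_radial = disp$top[["radial"]],
    hensen_top_vertical = disp$top[["vertical"]],
    hensen_side_radial = disp$side[["radial"]],
    hensen_side_vertical = disp$side[["vertical"]],
    alpha_deg = alpha,
    converged = state$converged
  )
}

#' OHC rotation with the reticular lamina held fixed
#'
#' For comparison with imaging experiments the somatic rotation angle is
#' also computed in a frame in which the reticular lamina does not move and
#' the hyperpolarised (elongated, epsilon = 0) configuration is the
#' reference: each deformed state is rigidly rotated about the RL pivot by
#' minus the RL rotation angle before measuring the OHC axis rotation.
#'
#' @param geometry an `oc_geometry`.
#' @param delta,gamma extensibilities (the elastica does not influence the
#'   rotation but is solved to guarantee a fully consistent state).
#' @param eps_range contraction range scanned from the hyperpolarised state
#'   (default 0 to 0.04, the maximal physiological contraction).
#' @param n number of grid points.
#' @param control solver settings.
#' @param fluid_only if TRUE skip the elastica stage (the rotation depends
#'   only on the fluid solve).
#' @return tibble with `epsilon` and `alpha_deg` (positive =
#'   counter-clockwise, i.e. base toward the stria for the default
#'   geometry).
#' @export
rotation_reference_variant <- function(geometry, delta = 1.15, gamma = 0.1,
                                       eps_range = c(0, 0.04), n = 9L,
                                       control = oc_control(),
                                       fluid_only = FALSE) {
  eps_grid <- seq(eps_range[1L], eps_range[2L], length.out = n)
  purrr::map_dfr(eps_grid, function(e) {
    if (e == 0) return(tibble::tibble(epsilon = 0, alpha_deg = 0))
    fs <- if (fluid_only) {
      solve_fluid_space(geometry, e, delta, control)
    } else {
      solve_deformation(geometry, e, delta, gamma, control)$fluid
    }
    th_rl <- signed_angle(geometry$ohc_apex_0 - geometry$pivot_rl,
                          fs$ohc_apex - geometry$pivot_rl)
    a2 <- rotate_about(fs$ohc_apex, geometry$pivot_rl, -th_rl)
    b2 <- rotate_about(fs$ohc_base, geometry$pivot_rl, -th_rl)
    tibble::tibble(
      epsilon = e,
      alpha_deg = signed_angle(geometry$ohc_base_0 - geometry$ohc_apex_0,
                               b2 - a2) * 180 / pi)
  })
}

## ---- broom-style methods and serialization ----------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname observables
#' @param x an `oc_deformation`.
#' @param ... unused.
#' @export
tidy.oc_deformation <- function(x, ...) observables(x)

#' One-row solver summary of a deformed state
#'
#' @param x an `oc_deformation`.
#' @param ... unused.
#' @export
glance.oc_deformation <- function(x, ...) {
  tibble::tibble(
    epsilon = x$params$epsilon, delta = x$params$delta, gamma = x$params$gamma,
    converged = x$converged,
    fluid_residual = x$residuals[["fluid"]],
    elastica_residual = x$residuals[["elastica"]],
    elastica_energy = x$contour$energy,
    continuation_steps = nrow(x$log),
    n_nodes = x$contour$n_nodes
  )
}

#' @export
print.oc_deformation <- function(x, ...) {
  cat(sprintf("<oc_deformation> eps %+.4g, Delta %.3f, Gamma %.3f (%s)\n",
              x$params$epsilon, x$params$delta, x$params$gamma,
              if (x$converged) "converged" else "NOT converged"))
  print(observables(x))
  invisible(x)
}

#' Serialize a deformed state to JSON
#'
#' Writes points, angle, areas, multipliers and residuals; a state written
#' and re-read reproduces observables bit-identically.
#'
#' @param state an `oc_deformation`.
#' @param path output JSON path.
#' @export
write_state <- function(state, path) {
  obj <- list(
    params = state$params[c("epsilon", "delta", "gamma")],
    fluid = list(ohc_apex = state$fluid$ohc_apex,
                 ohc_base = state$fluid$ohc_base,
                 phi = state$fluid$phi,
                 A_OT = state$fluid$A_OT, A_SN = state$fluid$A_SN,
                 A_TC = state$fluid$A_TC,
                 residuals = state$fluid$residuals),
    contour = list(phi_nodes = state$contour$phi_nodes,
                   arc_length = state$contour$arc_length,
                   ds = state$contour$ds,
                   gamma_eps = state$contour$gamma_eps,
                   multipliers = as.list(state$contour$multipliers),
                   energy = state$contour$energy,
                   residual = state$contour$residual,
                   anchor = state$contour$anchor,
                   L0 = state$contour$L0),
    observables = as.list(observables(state))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Export the contour node table as CSV
#'
#' Columns: arc length `s`, tangent angle `phi`, coordinates `x`, `y` per
#' node. Multipliers and residuals belong in the JSON state
#' ([write_state()]).
#'
#' @param contour an `oc_hensen_contour`.
#' @param path output CSV path.
#' @export
write_contour_csv <- function(contour, path) {
  n <- contour$n_nodes
  utils::write.csv(data.frame(
    s = seq(0, contour$arc_length, length.out = n + 1L),
    phi = contour$phi_nodes,
    x = contour$coords[, 1L],
    y = contour$coords[, 2L]
  ), path, row.names = FALSE)
  invisible(path)
}
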