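# ggplot2 displays for solved states, sweeps, region maps and gain curves.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Cross-section plot of a deformed state
#'
#' Draws the reference outline (grey) and the deformed configuration
#' (colour): tunnel of Corti, space-of-Nuel polygon, outer-tunnel arc,
#' Hensen contour, and the tracked material points. Displacements at
#' physiological contractions are sub-micrometre, so `exaggerate` scales
#' them for display purposes only.
#'
#' @param object an `oc_deformation`.
#' @param exaggerate display magnification of all displacements.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.oc_deformation <- function(object, exaggerate = 25, ...) {
  geom <- object$geometry
  tab <- contour_table(geom, object$contour$n_nodes)
  ref_arc <- arc_polyline(geom$ohc_apex_0, geom$ohc_base_0, geom$a_arc, geom$phi0, 180L)
  def_arc <- arc_polyline(object$fluid$ohc_apex, object$fluid$ohc_base,
                          geom$a_arc, object$fluid$phi, 180L)
  mag <- function(def, ref) ref + exaggerate * (def - ref)
  def_arc <- mag(def_arc, ref_arc)
  def_contour <- mag(object$contour$coords, tab$xy0)
  a <- mag(matrix(object$fluid$ohc_apex, 1L), matrix(geom$ohc_apex_0, 1L))
  b <- mag(matrix(object$fluid$ohc_base, 1L), matrix(geom$ohc_base_0, 1L))

  path_df <- function(xy, what, cfg) {
    tibble::tibble(x = xy[, 1L], y = xy[, 2L], what = what, cfg = cfg)
  }
  ref <- dplyr::bind_rows(
    path_df(rbind(geom$ip_foot, geom$pivot_rl, geom$op_foot, geom$ip_foot), "tunnel of Corti", "reference"),
    path_df(rbind(geom$pivot_rl, geom$ohc_apex_0, geom$ohc_base_0, geom$dc_anchor), "RL / OHC / DC", "reference"),
    path_df(ref_arc, "outer tunnel", "reference"),
    path_df(tab$xy0, "Hensen contour", "reference"))
  def <- dplyr::bind_rows(
    path_df(rbind(geom$pivot_rl, a, b, geom$dc_anchor), "RL / OHC / DC", "deformed"),
    path_df(def_arc, "outer tunnel", "deformed"),
    path_df(def_contour, "Hensen contour", "deformed"))

  ggplot2::ggplot(dplyr::bind_rows(ref, def),
                  ggplot2::aes(.data$x, .data$y, group = interaction(.data$what, .data$cfg),
                               colour = .data$cfg)) +
    ggplot2::geom_path(linewidth = 0.5) +
    ggplot2::scale_colour_manual(values = c(reference = "grey60", deformed = "#D55E00")) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "radial position (µm, toward stria)",
      y = "vertical position (µm, toward scala vestibuli)",
      colour = NULL,
      title = sprintf("organ of Corti deformation (ε = %.3g, Δ = %.2f, Γ = %.2f; ×%g display)",
                      object$params$epsilon, object$params$delta,
                      object$params$gamma, exaggerate)) +
    ggplot2::theme_minimal()
}

#' Displacement-vs-contraction curves of a sweep
#'
#' @param object an `oc_sweep` from [sweep_contraction()].
#' @param ... unused.
#' @export
autoplot.oc_sweep <- function(object, ...) {
  long <- tidyr_pivot(object)
  ggplot2::ggplot(long, ggplot2::aes(.data$epsilon, .data$displacement,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "OHC contraction ε", y = "displacement (µm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

# minimal long-format helper (avoids a tidyr dependency)
tidyr_pivot <- function(sweep) {
  cols <- c("d_rl", "hensen_top_radial", "hensen_top_vertical",
            "hensen_side_radial", "hensen_side_vertical")
  purrr::map_dfr(cols, function(cl) {
    tibble::tibble(epsilon = sweep$epsilon, quantity = cl,
                   displacement = sweep[[cl]])
  })
}

#' Tile map of the (Delta, Gamma) classification
#'
#' @param region an `oc_region_map` from [classify_parameter_region()].
#' @param fill which column to display (default the sign of the top point's
#'   radial displacement).
#' @export
plot_region_map <- function(region, fill = "hensen_top_radial") {
  region$display <- dplyr::case_when(
    !region$solvable_at_probe ~ "no solution",
    region[[fill]] < 0 ~ paste(fill, "< 0"),
    TRUE ~ paste(fill, "≥ 0"))
  ggplot2::ggplot(region, ggplot2::aes(.data$gamma, .data$delta, fill = .data$display)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "Γ (Hensen extensibility)", y = "Δ (Deiters' extensibility)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Gain versus operating point
#'
#' @param geometry an `oc_geometry`.
#' @param delta,gamma extensibilities.
#' @param eps0_grid operating points to evaluate.
#' @param control solver settings.
#' @export
plot_gain_curve <- function(geometry, delta = 1.15, gamma = 0.1,
                            eps0_grid = seq(-0.02, 0.02, by = 0.004),
                            control = oc_control()) {
  df <- tibble::tibble(
    eps0 = eps0_grid,
    gain = vapply(eps0_grid, function(e) rl_gain(geometry, delta, gamma, e,
                                                 control = control), numeric(1L)))
  ggplot2::ggplot(df, ggplot2::aes(.data$eps0, .data$gain)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "resting contraction ε⁰",
                  y = "dD_RL/dε (µm per unit contraction)") +
    ggplot2::theme_minimal()
}
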