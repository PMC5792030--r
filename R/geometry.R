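# Reference cross-section geometry of the apical organ of Corti.
#
# The geometry is fully config-driven. A config lists the fixed landmarks
# (pivot of the reticular lamina at the outer-pillar apex, Deiters'-cell
# anchor on the basilar membrane, pillar feet), the resting lengths and
# angles, and a polynomial description of the Hensen-cell contour. All
# derived quantities (OHC endpoints, outer-tunnel arc length, reference
# areas, discretised contour tables) are computed and cached at build time.

GEOM_TOL <- 0.1  # um; landmark/length consistency tolerance for configs

#' Build and validate a reference organ-of-Corti cross-section
#'
#' Constructs the fixed reference geometry from a morphometric parameter set
#' and validates its internal consistency: positive lengths, the
#' outer-tunnel chord relation \eqn{L_{OHC,0} = a\,\sin\varphi_0/\varphi_0},
#' a simple (non-self-intersecting) Hensen contour that reaches the OHC apex,
#' and strictly positive areas of all compartments.
#'
#' @param config a geometry config as produced by [geometry_config()] or
#'   read with [read_geometry()]. Must carry `units = "um"`.
#' @return An object of class `oc_geometry`: landmarks, resting lengths,
#'   reference angles and areas, plus a cache of discretised contour tables.
#' @examples
#' geom <- build_reference_geometry(default_fixture())
#' geom$L_OHC0
#' @export
build_reference_geometry <- function(config) {
  cfg <- canonical_config(config)

  bm_axis <- cfg$bm_axis / sqrt(sum(cfg$bm_axis^2))
  bm_normal <- rot90ccw(bm_axis)
  theta_bm <- atan2(bm_axis[2L], bm_axis[1L])

  th <- cfg$rl_bm_angle_deg * pi / 180
  dir_rl <- c(cos(theta_bm + th), sin(theta_bm + th))
  ang_ohc <- theta_bm + th - pi / 2 + cfg$ohc_tilt_deg * pi / 180
  dir_ohc <- c(cos(ang_ohc), sin(ang_ohc))

  pivot <- cfg$pivot_rl
  a0 <- pivot + cfg$l_rl * dir_rl
  b0 <- a0 + cfg$l_ohc * dir_ohc

  if (!is.null(cfg$ohc_apex)) {
    check_landmark("ohc_apex", cfg$ohc_apex, a0)
    a0 <- cfg$ohc_apex
  }
  if (!is.null(cfg$ohc_base)) {
    d <- sqrt(sum((a0 - cfg$ohc_base)^2))
    if (abs(d - cfg$l_ohc) > GEOM_TOL) {
      stop(sprintf(paste0("geometry invariant violated: |ohc_apex - ohc_base| = %.4f um ",
                          "inconsistent with L_OHC0 = %.4f um (tolerance %.2f um)"),
                   d, cfg$l_ohc, GEOM_TOL), call. = FALSE)
    }
    b0 <- cfg$ohc_base
  }

  if (!(cfg$phi0 > 0 && cfg$phi0 < pi)) {
    stop("geometry invariant violated: phi0 must lie in (0, pi)", call. = FALSE)
  }
  lengths <- c(l_rl = cfg$l_rl, l_ohc = cfg$l_ohc)
  if (any(lengths <= 0)) stop("geometry invariant violated: lengths must be positive", call. = FALSE)

  dc <- cfg$dc_anchor
  L_DC0 <- sqrt(sum((b0 - dc)^2))
  a_arc <- cfg$l_ohc * cfg$phi0 / sin(cfg$phi0)

  tc <- rbind(cfg$inner_pillar_foot, cfg$outer_pillar_foot, pivot)
  A_TC <- polygon_area(tc)

  geom <- structure(list(
    config = cfg,
    bm_axis = bm_axis, bm_normal = bm_normal,
    pivot_rl = pivot, ohc_apex_0 = a0, ohc_base_0 = b0,
    dc_anchor = dc, op_foot = cfg$outer_pillar_foot, ip_foot = cfg$inner_pillar_foot,
    tc_vertices = tc,
    nuel_fixed_vertices = rbind(pivot, dc, cfg$outer_pillar_foot),
    nuel_splice_after = 1L,
    L_RL = cfg$l_rl, L_OHC0 = cfg$l_ohc, L_DC0 = L_DC0,
    phi0 = cfg$phi0, a_arc = a_arc,
    rl_bm_angle = cfg$rl_bm_angle_deg,
    hensen_anchor = unname(poly_curve_eval(cfg$hensen_coeffs, 0)[1L, ]),
    hensen_coeffs = cfg$hensen_coeffs,
    tracked_fractions = cfg$tracked_fractions,
    A_TC = A_TC,
    cache = new.env(parent = emptyenv())
  ), class = "oc_geometry")

  geom$A_SN0 <- polygon_area(nuel_polygon(geom, a0, b0))
  geom$A_OT0 <- outer_tunnel_area(a_arc, cfg$phi0)

  # chord identity holds by construction; keep the assertion as a guard
  stopifnot(abs(chord_length(a_arc, cfg$phi0) - cfg$l_ohc) < 1e-9 * cfg$l_ohc)

  # build (and thereby validate) the default-resolution contour table
  tab <- contour_table(geom, n_nodes = cfg$n_nodes)
  geom$L_HC0 <- tab$L0
  geom$A_HC0 <- tab$A_HC

  if (any(c(geom$A_TC, geom$A_SN0, geom$A_OT0, geom$A_HC0) <= 0)) {
    stop("geometry invariant violated: all reference areas must be positive", call. = FALSE)
  }
  geom
}

#' @export
print.oc_geometry <- function(x, ...) {
  cat("<oc_geometry> apical organ-of-Corti cross-section (um)\n")
  cat(sprintf("  RL pivot (%.2f, %.2f), OHC apex (%.2f, %.2f), base (%.2f, %.2f)\n",
              x$pivot_rl[1], x$pivot_rl[2], x$ohc_apex_0[1], x$ohc_apex_0[2],
              x$ohc_base_0[1], x$ohc_base_0[2]))
  cat(sprintf("  L_RL %.2f  L_OHC0 %.2f  L_DC0 %.2f  L_HC0 %.2f\n",
              x$L_RL, x$L_OHC0, x$L_DC0, x$L_HC0))
  cat(sprintf("  phi0 %.3f rad  arc %.2f  BM-RL angle %.2f deg\n",
              x$phi0, x$a_arc, x$rl_bm_angle))
  cat(sprintf("  areas: TC %.1f  SN %.1f  OT %.1f  HC %.1f\n",
              x$A_TC, x$A_SN0, x$A_OT0, x$A_HC0))
  invisible(x)
}

check_landmark <- function(name, given, derived) {
  d <- sqrt(sum((given - derived)^2))
  if (d > GEOM_TOL) {
    stop(sprintf(paste0("geometry invariant violated: configured %s is %.4f um from the ",
                        "position implied by lengths/angles (tolerance %.2f um)"),
                 name, d, GEOM_TOL), call. = FALSE)
  }
  invisible(TRUE)
}

# Space-of-Nuel polygon with the OHC endpoints spliced into the fixed
# vertex list (after the RL pivot): pivot, apex, base, Deiters' anchor,
# outer-pillar foot.
nuel_polygon <- function(geom, a, b) {
  fixed <- geom$nuel_fixed_vertices
  k <- geom$nuel_splice_after
  rbind(fixed[seq_len(k), , drop = FALSE], a, b,
        fixed[-seq_len(k), , drop = FALSE])
}

## ---- geometry config --------------------------------------------------

#' Assemble a geometry config
#'
#' A geometry config is a named list of morphometric parameters with an
#' explicit `units` field ("um"). Coordinates are in the cross-sectional
#' plane; `bm_axis` defines the basilar-membrane direction (radial axis,
#' abneural positive) so a rigidly rotated config describes the same organ.
#'
#' @param pivot_rl apex of the outer pillar cell; rotation centre of the
#'   rigid reticular lamina (um).
#' @param rl_bm_angle_deg inclination of the basilar membrane with respect to
#'   the reticular lamina, degrees.
#' @param l_rl reticular-lamina arm length from pivot to OHC apex (um).
#' @param l_ohc resting length of the lumped OHC row (um).
#' @param ohc_tilt_deg tilt of the OHC axis relative to the perpendicular to
#'   the reticular lamina, degrees (positive tilts the base abneurally).
#' @param dc_anchor Deiters'-cell attachment on the basilar membrane (um).
#' @param outer_pillar_foot,inner_pillar_foot feet of the pillar cells on the
#'   basilar membrane; together with `pivot_rl` they form the rigid tunnel
#'   of Corti triangle (um).
#' @param phi0 reference angle between the OHC and the outer-tunnel arc,
#'   radians, in (0, pi).
#' @param hensen_control_points Bezier control points of the reference
#'   Hensen-cell contour, first row at the abneural anchor, last row at the
#'   OHC apex (um). Alternatively supply `hensen_coeffs`.
#' @param hensen_coeffs power-basis polynomial coefficients (list with `x`,
#'   `y`) of the parametric reference contour over t in \[0, 1\].
#' @param tracked_fractions reference arc-length fractions of the two tracked
#'   Hensen material points (named `top` and `side`).
#' @param n_nodes number of elastica elements N used by default (the contour
#'   carries N + 1 nodes).
#' @param bm_axis basilar-membrane direction (unit vector; default c(1, 0)).
#' @param ohc_apex,ohc_base optional explicit OHC endpoint coordinates; if
#'   given they are validated against the lengths above (0.1 um tolerance).
#' @return a config list suitable for [build_reference_geometry()].
#' @export
geometry_config <- function(pivot_rl, rl_bm_angle_deg, l_rl, l_ohc,
                            ohc_tilt_deg, dc_anchor, outer_pillar_foot,
                            inner_pillar_foot, phi0,
                            hensen_control_points = NULL,
                            hensen_coeffs = NULL,
                            tracked_fractions = list(top = 0.55, side = 0.2),
                            n_nodes = 100L, bm_axis = c(1, 0),
                            ohc_apex = NULL, ohc_base = NULL) {
  cfg <- list(
    units = "um",
    pivot_rl = as.numeric(pivot_rl),
    rl_bm_angle_deg = rl_bm_angle_deg,
    l_rl = l_rl, l_ohc = l_ohc, ohc_tilt_deg = ohc_tilt_deg,
    dc_anchor = as.numeric(dc_anchor),
    outer_pillar_foot = as.numeric(outer_pillar_foot),
    inner_pillar_foot = as.numeric(inner_pillar_foot),
    phi0 = phi0,
    hensen_control_points = if (!is.null(hensen_control_points)) {
      m <- as.matrix(hensen_control_points); dimnames(m) <- NULL; m
    },
    hensen_coeffs = hensen_coeffs,
    tracked_fractions = tracked_fractions,
    n_nodes = as.integer(n_nodes),
    bm_axis = as.numeric(bm_axis),
    ohc_apex = if (!is.null(ohc_apex)) as.numeric(ohc_apex),
    ohc_base = if (!is.null(ohc_base)) as.numeric(ohc_base)
  )
  canonical_config(cfg)
}

canonical_config <- function(cfg) {
  if (inherits(cfg, "oc_geometry")) cfg <- cfg$config
  if (is.null(cfg$units)) {
    stop("geometry config must declare its units (expected 'um')", call. = FALSE)
  }
  if (!identical(cfg$units, "um")) {
    stop(sprintf("unsupported geometry units '%s' (expected 'um')", cfg$units),
         call. = FALSE)
  }
  if (is.null(cfg$bm_axis)) cfg$bm_axis <- c(1, 0)
  if (is.null(cfg$n_nodes)) cfg$n_nodes <- 100L
  if (is.null(cfg$tracked_fractions)) {
    cfg$tracked_fractions <- list(top = 0.55, side = 0.2)
  }
  for (f in c("pivot_rl", "dc_anchor", "outer_pillar_foot", "inner_pillar_foot",
              "bm_axis", "ohc_apex", "ohc_base")) {
    if (!is.null(cfg[[f]])) cfg[[f]] <- as.numeric(unlist(cfg[[f]]))
  }
  if (!is.null(cfg$hensen_control_points)) {
    m <- cfg$hensen_control_points
    if (is.list(m)) m <- do.call(rbind, lapply(m, as.numeric))
    m <- as.matrix(m); dimnames(m) <- NULL
    cfg$hensen_control_points <- m
    cfg$hensen_coeffs <- bezier_to_poly(m)
  } else if (!is.null(cfg$hensen_coeffs)) {
    cfg$hensen_coeffs <- lapply(cfg$hensen_coeffs, as.numeric)
  } else {
    stop("geometry config needs a Hensen contour description ",
         "(hensen_control_points or hensen_coeffs)", call. = FALSE)
  }
  cfg
}

## ---- serialization ----------------------------------------------------

#' Read / write geometry configs
#'
#' Configs are stored as YAML (default) or JSON, chosen by file extension.
#' Numbers are written at full double precision so a config round-trips
#' losslessly and a geometry rebuilt from a serialized config reproduces all
#' derived fields bit-identically.
#'
#' @param x an `oc_geometry` or a geometry config list.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_geometry()` returns an `oc_geometry`;
#'   `write_geometry()` returns `path` invisibly.
#' @export
write_geometry <- function(x, path) {
  cfg <- canonical_config(x)
  cfg$hensen_coeffs <- NULL   # derived from control points when present
  if (is.null(cfg$hensen_control_points)) {
    cfg$hensen_coeffs <- canonical_config(x)$hensen_coeffs
  }
  ser <- cfg
  if (!is.null(ser$hensen_control_points)) {
    ser$hensen_control_points <- apply(ser$hensen_control_points, 1L, as.numeric,
                                       simplify = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    writeLines(yaml::as.yaml(ser, precision = 17L), path)
  } else if (ext == "json") {
    jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    stop("unsupported geometry file extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported geometry file extension: ", ext, call. = FALSE)
  }
  build_reference_geometry(cfg)
}

## ---- reference contour ------------------------------------------------

#' Tangent-angle table of a polynomial reference contour
#'
#' Reparametrises a parametric polynomial curve by arc length and tabulates
#' its tangent angle \eqn{\phi_0(s)} at `n_nodes + 1` equispaced nodes, the
#' discretisation consumed by the Hensen elastica solver.
#'
#' @param coeffs power-basis coefficients (list with `x` and `y`) of the
#'   curve over t in \[0, 1\], or a function `f(t)` returning an
#'   (length(t) x 2) coordinate matrix (useful for non-polynomial oracles).
#' @param anchor,apex expected curve endpoints (um); the curve must connect
#'   them (0.1 um tolerance) or an error is raised.
#' @param n_nodes number of arc-length elements (>= 50 for solver use).
#' @param samples number of parameter samples used for the arc-length
#'   reparametrisation.
#' @return list with `phi` (tangent angles at the nodes, radians, unwrapped),
#'   `L0` (total arc length, um), `ds` (node spacing) and `kappa0_start`
#'   (curvature at s = 0).
#' @export
reference_contour_from_polynomial <- function(coeffs, anchor, apex,
                                              n_nodes = 100L, samples = 20000L) {
  if (is.function(coeffs)) {
    fe <- coeffs
    fd <- function(t) {
      h <- 1e-7
      (fe(pmin(t + h, 1)) - fe(pmax(t - h, 0))) / (pmin(t + h, 1) - pmax(t - h, 0))
    }
  } else {
    fe <- function(t) poly_curve_eval(coeffs, t)
    fd <- function(t) poly_curve_deriv(coeffs, t)
  }
  p0 <- fe(0); p1 <- fe(1)
  if (sqrt(sum((p0 - anchor)^2)) > GEOM_TOL) {
    stop("contour curve does not start at the anchor", call. = FALSE)
  }
  if (sqrt(sum((p1 - apex)^2)) > GEOM_TOL) {
    stop("contour curve fails to reach the apex", call. = FALSE)
  }

  t <- seq(0, 1, length.out = samples + 1L)
  d <- fd(t)
  speed <- sqrt(rowSums(d^2))
  if (any(speed < 1e-12)) {
    stop("contour parametrisation is singular (zero speed)", call. = FALSE)
  }
  s <- trapz_cum(speed, 1 / samples)
  L0 <- s[length(s)]
  if (any(diff(s) <= 0)) {
    stop("contour must progress monotonically from anchor to apex", call. = FALSE)
  }

  si <- seq(0, L0, length.out = n_nodes + 1L)
  ti <- approx(s, t, xout = si, ties = "ordered")$y
  di <- fd(ti)
  phi <- atan2(di[, 2L], di[, 1L])
  dp <- diff(phi)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  phi <- cumsum(c(phi[1L], dp))

  # curvature at s = 0 from tangent angles at two nearby interior
  # parameters (second-order in h, robust for function inputs too)
  h <- 1e-5
  dd <- fd(c(h, 2 * h))
  ph <- atan2(dd[, 2L], dd[, 1L])
  kappa0 <- (ph[2L] - ph[1L]) / (sqrt(sum(((dd[1L, ] + dd[2L, ]) / 2)^2)) * h)

  list(phi = phi, L0 = L0, ds = L0 / n_nodes, kappa0_start = kappa0)
}

# Discretised, projected reference contour plus reference boundary
# functionals, cached per node count on the geometry object.
contour_table <- function(geom, n_nodes = geom$config$n_nodes) {
  key <- paste0("N", n_nodes)
  if (!is.null(geom$cache[[key]])) return(geom$cache[[key]])
  if (n_nodes < 50L) stop("contour discretisation needs n_nodes >= 50", call. = FALSE)

  anchor <- unname(poly_curve_eval(geom$hensen_coeffs, 0)[1L, ])
  raw <- reference_contour_from_polynomial(geom$hensen_coeffs, anchor,
                                           geom$ohc_apex_0, n_nodes)

  # Project the raw tangent table onto the discrete constraint set so that
  # the trapezoid-quadrature endpoint coincides exactly with the OHC apex.
  # The projected table is the reference configuration of the discrete
  # problem: at eps = 0 it is feasible with zero bending energy, so the
  # solver returns it identically.
  proj <- project_reference_contour(raw, geom$ohc_apex_0 - anchor)

  ds0 <- raw$L0 / n_nodes
  xy0 <- cbind(anchor[1L] + trapz_cum(cos(proj$phi), ds0),
               anchor[2L] + trapz_cum(sin(proj$phi), ds0))
  S0 <- polyline_ydx(xy0)

  arc0 <- arc_polyline(geom$ohc_apex_0, geom$ohc_base_0, geom$a_arc, geom$phi0)
  phie_off <- proj$phi[n_nodes + 1L] -
    arc_tangent_at_apex(geom$ohc_apex_0, geom$ohc_base_0, geom$a_arc, geom$phi0)
  S_other0 <- polyline_ydx(arc0) +
    segment_ydx(geom$ohc_base_0, geom$dc_anchor) +
    segment_ydx(geom$dc_anchor, anchor)

  loop <- rbind(xy0, arc0[-1L, ], geom$dc_anchor, anchor)
  A_HC <- polygon_area(loop)

  validate_contour(geom, xy0, arc0, n_nodes)

  tab <- list(N = n_nodes, L0 = raw$L0, ds0 = ds0,
              phi0 = proj$phi, kappa0_start = raw$kappa0_start,
              anchor = anchor, xy0 = xy0, S0 = S0, S_other0 = S_other0,
              phie_off = phie_off, A_HC = A_HC)
  geom$cache[[key]] <- tab
  tab
}

validate_contour <- function(geom, xy0, arc0, n_nodes) {
  # simple-curve check: no self intersection of the contour polyline
  if (polyline_self_intersects(xy0)) {
    stop("geometry error: Hensen contour is self-intersecting", call. = FALSE)
  }
  # the contour must stay outside the outer-tunnel circle wherever it lies
  # within the arc's swept sector (the two curves share the OHC apex and
  # form a thin wedge there; the endpoint itself sits on the circle)
  clear <- arc_sector_clearance(xy0[-(n_nodes + 1L), , drop = FALSE],
                                geom$ohc_apex_0, geom$ohc_base_0,
                                geom$a_arc, geom$phi0)
  if (any(clear < -1e-6)) {
    stop("geometry error: Hensen contour crosses the outer-tunnel arc", call. = FALSE)
  }
  invisible(TRUE)
}

# Vectorised strict-crossing test between all segment pairs of two
# polylines (shared endpoints / touching do not count as crossings).
polylines_cross <- function(p, q) {
  px1 <- p[-nrow(p), 1L]; py1 <- p[-nrow(p), 2L]
  px2 <- p[-1L, 1L];      py2 <- p[-1L, 2L]
  qx1 <- q[-nrow(q), 1L]; qy1 <- q[-nrow(q), 2L]
  qx2 <- q[-1L, 1L];      qy2 <- q[-1L, 2L]
  ex <- qx2 - qx1; ey <- qy2 - qy1   # length n
  d1 <- sweep(outer(py1, qy1, "-"), 2L, ex, "*") - sweep(outer(px1, qx1, "-"), 2L, ey, "*")
  d2 <- sweep(outer(py2, qy1, "-"), 2L, ex, "*") - sweep(outer(px2, qx1, "-"), 2L, ey, "*")
  fx <- px2 - px1; fy <- py2 - py1   # length m
  d3 <- sweep(outer(py1, qy1, function(a, b) b - a), 1L, fx, "*") -
        sweep(outer(px1, qx1, function(a, b) b - a), 1L, fy, "*")
  d4 <- sweep(outer(py1, qy2, function(a, b) b - a), 1L, fx, "*") -
        sweep(outer(px1, qx2, function(a, b) b - a), 1L, fy, "*")
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

polyline_self_intersects <- function(xy) {
  n <- nrow(xy) - 1L
  for (i in seq_len(n - 2L)) {
    if (polylines_cross(xy[i:(i + 1L), , drop = FALSE],
                        xy[(i + 2L):(n + 1L), , drop = FALSE])) {
      return(TRUE)
    }
  }
  FALSE
}
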