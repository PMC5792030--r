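# Shared fixtures for the test suite. Expensive objects (geometry builds,
# full solves) are memoised per session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

test_geometry <- function() memo("geom", default_geometry())

# fitted parameters of the model: Delta = 1.15, Gamma = 0.1
fitted_state <- function(epsilon = 0.005) {
  memo(paste0("fit", epsilon),
       solve_deformation(test_geometry(), epsilon, 1.15, 0.1))
}

# config with every coordinate/length scaled by k (angles untouched)
scaled_config <- function(k) {
  cfg <- default_fixture()
  cfg <- cortikin:::canonical_config(cfg)
  for (f in c("pivot_rl", "dc_anchor", "outer_pillar_foot", "inner_pillar_foot")) {
    cfg[[f]] <- cfg[[f]] * k
  }
  cfg$l_rl <- cfg$l_rl * k
  cfg$l_ohc <- cfg$l_ohc * k
  cfg$hensen_control_points <- cfg$hensen_control_points * k
  cfg$hensen_coeffs <- bezier_to_poly(cfg$hensen_control_points)
  cfg
}

# config rigidly rotated by angle theta about the origin (bm_axis rotated too)
rotated_config <- function(theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
  cfg <- cortikin:::canonical_config(default_fixture())
  for (f in c("pivot_rl", "dc_anchor", "outer_pillar_foot", "inner_pillar_foot",
              "bm_axis")) {
    cfg[[f]] <- as.numeric(R %*% cfg[[f]])
  }
  cfg$hensen_control_points <- t(R %*% t(cfg$hensen_control_points))
  cfg$hensen_coeffs <- bezier_to_poly(cfg$hensen_control_points)
  cfg
}

# Monte-Carlo point-in-polygon area estimate (crossing number, vectorised
# over points, chunked to bound memory)
mc_polygon_area <- function(poly, n = 1e6, seed = 42L, chunk = 250000L) {
  set.seed(seed)
  xr <- range(poly[, 1L]); yr <- range(poly[, 2L])
  ex <- poly[-1L, 1L]; ey <- poly[-1L, 2L]
  sx <- poly[-nrow(poly), 1L]; sy <- poly[-nrow(poly), 2L]
  hits <- 0
  done <- 0
  while (done < n) {
    m <- min(chunk, n - done)
    px <- runif(m, xr[1L], xr[2L]); py <- runif(m, yr[1L], yr[2L])
    crossings <- integer(m)
    for (i in seq_along(sx)) {
      straddles <- (sy[i] > py) != (ey[i] > py)
      if (any(straddles)) {
        xint <- sx[i] + (py[straddles] - sy[i]) * (ex[i] - sx[i]) / (ey[i] - sy[i])
        idx <- which(straddles)[xint > px[straddles]]
        crossings[idx] <- crossings[idx] + 1L
      }
    }
    hits <- hits + sum(crossings %% 2L == 1L)
    done <- done + m
  }
  diff(xr) * diff(yr) * hits / n
}

# closed boundary polygon of the Hensen region for a solved state
hensen_loop <- function(geometry, state) {
  tab <- cortikin:::contour_table(geometry, state$contour$n_nodes)
  arc <- cortikin:::arc_polyline(state$fluid$ohc_apex, state$fluid$ohc_base,
                                 geometry$a_arc, state$fluid$phi)
  rbind(state$contour$coords, arc[-1L, ], geometry$dc_anchor, tab$anchor)
}

hensen_loop_reference <- function(geometry, n_nodes = geometry$config$n_nodes) {
  tab <- cortikin:::contour_table(geometry, n_nodes)
  arc <- cortikin:::arc_polyline(geometry$ohc_apex_0, geometry$ohc_base_0,
                                 geometry$a_arc, geometry$phi0)
  rbind(tab$xy0, arc[-1L, ], geometry$dc_anchor, tab$anchor)
}
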