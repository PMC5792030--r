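test_that("reference geometry satisfies its construction invariants", {
  geom <- test_geometry()

  # chord relation of the outer tunnel holds to machine precision
  expect_equal(chord_length(geom$a_arc, geom$phi0), geom$L_OHC0,
               tolerance = 1e-12)
  # landmark/length consistency
  expect_equal(sqrt(sum((geom$pivot_rl - geom$ohc_apex_0)^2)), geom$L_RL,
               tolerance = 1e-12)
  expect_equal(sqrt(sum((geom$ohc_apex_0 - geom$ohc_base_0)^2)), geom$L_OHC0,
               tolerance = 1e-12)
  expect_equal(sqrt(sum((geom$dc_anchor - geom$ohc_base_0)^2)), geom$L_DC0,
               tolerance = 1e-12)
  # all compartment areas strictly positive
  expect_true(all(c(geom$A_TC, geom$A_SN0, geom$A_OT0, geom$A_HC0) > 0))
  # the projected reference contour lands exactly on the OHC apex
  tab <- cortikin:::contour_table(geom)
  expect_equal(tab$xy0[tab$N + 1L, ], geom$ohc_apex_0, tolerance = 1e-10)
})

test_that("inconsistent configs are rejected with a named invariant", {
  cfg <- cortikin:::canonical_config(default_fixture())
  # OHC base displaced so |a0 - b0| disagrees with L_OHC0 by > 0.1 um
  th <- cfg$rl_bm_angle_deg * pi / 180
  apex <- cfg$pivot_rl + cfg$l_rl * c(cos(th), sin(th))
  ang <- th - pi / 2 + cfg$ohc_tilt_deg * pi / 180
  cfg$ohc_base <- apex + (cfg$l_ohc + 0.2) * c(cos(ang), sin(ang))
  expect_error(build_reference_geometry(cfg), "inconsistent with L_OHC0")

  cfg2 <- cortikin:::canonical_config(default_fixture())
  cfg2$phi0 <- 3.5
  expect_error(build_reference_geometry(cfg2), "phi0")

  cfg3 <- default_fixture()
  cfg3$units <- NULL
  expect_error(build_reference_geometry(cfg3), "units")
})

test_that("Hensen enclosed area matches a Monte-Carlo point-in-region oracle", {
  geom <- test_geometry()
  tab <- cortikin:::contour_table(geom)
  # coarser arc polyline keeps the point-in-polygon loop cheap; its
  # polygonisation bias is far below the 0.1% tolerance
  arc <- cortikin:::arc_polyline(geom$ohc_apex_0, geom$ohc_base_0,
                                 geom$a_arc, geom$phi0, 180L)
  loop <- rbind(tab$xy0, arc[-1L, ], geom$dc_anchor, tab$anchor)
  mc <- mc_polygon_area(loop, n = 4e6)
  expect_equal(mc, geom$A_HC0, tolerance = 1e-3)
})

test_that("tangent-angle tables recover straight lines and circle arcs", {
  # degree-1 polynomial: straight segment, constant angle, exact length
  anchor <- c(2, 1); apex <- c(10, 7)
  tab <- reference_contour_from_polynomial(
    list(x = c(anchor[1], apex[1] - anchor[1]),
         y = c(anchor[2], apex[2] - anchor[2])),
    anchor, apex, n_nodes = 60L)
  expect_equal(tab$L0, sqrt(sum((apex - anchor)^2)), tolerance = 1e-9)
  expect_equal(diff(range(tab$phi)), 0, tolerance = 1e-9)
  expect_equal(tab$phi[1L], atan2(6, 8), tolerance = 1e-9)

  # quarter circle (function input): phi linear in s, curvature 1/r
  r <- 5
  quarter <- function(t) cbind(r * cos(pi / 2 * t), r * sin(pi / 2 * t))
  tabc <- reference_contour_from_polynomial(quarter, c(r, 0), c(0, r),
                                            n_nodes = 80L)
  expect_equal(tabc$L0, pi * r / 2, tolerance = 1e-6)
  s <- seq(0, tabc$L0, length.out = 81L)
  expect_equal(tabc$phi, pi / 2 + s / r, tolerance = 1e-5)
  expect_equal(tabc$kappa0_start, 1 / r, tolerance = 1e-4)
})

test_that("default contour arc length matches adaptive quadrature", {
  geom <- test_geometry()
  co <- geom$hensen_coeffs
  speed <- function(t) {
    d <- cortikin:::poly_curve_deriv(co, t)
    sqrt(rowSums(d^2))
  }
  L_quad <- integrate(speed, 0, 1, rel.tol = 1e-12)$value
  tab <- reference_contour_from_polynomial(co, geom$hensen_anchor,
                                           geom$ohc_apex_0, 100L)
  expect_equal(tab$L0, L_quad, tolerance = 1e-6)
})

test_that("a curve that misses the apex is rejected", {
  geom <- test_geometry()
  expect_error(
    reference_contour_from_polynomial(
      list(x = c(geom$hensen_anchor[1], 5), y = c(geom$hensen_anchor[2], 5)),
      geom$hensen_anchor, geom$ohc_apex_0, 60L),
    "fails to reach")
})

test_that("serialisation round-trips losslessly and rebuilds bit-identically", {
  geom <- test_geometry()
  path <- tempfile(fileext = ".yaml")
  write_geometry(geom, path)
  geom2 <- read_geometry(path)
  for (f in c("pivot_rl", "ohc_apex_0", "ohc_base_0", "dc_anchor",
              "L_RL", "L_OHC0", "L_DC0", "L_HC0", "phi0", "a_arc",
              "A_TC", "A_SN0", "A_OT0", "A_HC0")) {
    expect_identical(geom2[[f]], geom[[f]], label = f)
  }
  tab <- cortikin:::contour_table(geom)
  tab2 <- cortikin:::contour_table(geom2)
  expect_identical(tab2$phi0, tab$phi0)

  # JSON route round-trips too
  pj <- tempfile(fileext = ".json")
  write_geometry(geom, pj)
  geom3 <- read_geometry(pj)
  expect_equal(geom3$A_HC0, geom$A_HC0, tolerance = 1e-12)
})

test_that("scaling coordinates scales lengths by k and areas by k^2", {
  k <- 2.5
  geom <- test_geometry()
  gk <- build_reference_geometry(scaled_config(k))
  for (f in c("L_RL", "L_OHC0", "L_DC0", "L_HC0", "a_arc")) {
    expect_equal(gk[[f]], k * geom[[f]], tolerance = 1e-9, label = f)
  }
  for (f in c("A_TC", "A_SN0", "A_OT0", "A_HC0")) {
    expect_equal(gk[[f]], k^2 * geom[[f]], tolerance = 1e-8, label = f)
  }
  expect_equal(gk$phi0, geom$phi0)
  expect_equal(gk$rl_bm_angle, geom$rl_bm_angle)
})
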