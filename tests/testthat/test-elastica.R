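test_that("discrete curvature energy matches closed forms and an independent sum", {
  # preferred shape: zero energy
  phi0 <- seq(0.2, 1.4, length.out = 101L)
  expect_identical(discrete_curvature_energy(phi0, phi0, 1, 0.05), 0)

  # straight reference deformed into a circular arc of curvature kappa:
  # every increment deviates by kappa, so E = L kappa^2 / 2 exactly
  N <- 100L; L <- 12; kappa <- 0.3
  ds <- L / N
  straight <- rep(0.4, N + 1L)
  arc <- 0.4 + kappa * seq(0, L, length.out = N + 1L)
  expect_equal(discrete_curvature_energy(arc, straight, 1, ds),
               L * kappa^2 / 2, tolerance = 1e-12)

  # random perturbation vs an independent elementwise summation
  set.seed(11)
  phi <- phi0 + rnorm(101L, sd = 0.05)
  g_eps <- 1.0007
  manual <- 0
  for (i in 1:100) {
    e_i <- (phi[i + 1L] - phi[i]) / 0.05 - g_eps * (phi0[i + 1L] - phi0[i]) / 0.05
    manual <- manual + 0.05 / 2 * e_i^2
  }
  expect_equal(discrete_curvature_energy(phi, phi0, g_eps, 0.05), manual,
               tolerance = 1e-12)
  expect_error(discrete_curvature_energy(phi[-1L], phi0, 1, 0.05), "equal length")
})

test_that("area constant reduces to the reference integral at eps = 0", {
  geom <- test_geometry()
  fs0 <- solve_fluid_space(geom, 0, 1.15)
  tab <- cortikin:::contour_table(geom)
  expect_equal(area_constant_for(geom, fs0), tab$S0, tolerance = 1e-9)
})

test_that("the composite Hensen boundary conserves the enclosed area", {
  geom <- test_geometry()
  A_ref <- polygon_area(hensen_loop_reference(geom))
  for (pars in list(c(0.005, 1.15, 0.1), c(0.01, 1.15, 0.1),
                    c(0.005, 0.8, 0.2), c(-0.01, 1.15, 0.1))) {
    st <- solve_deformation(geom, pars[1L], pars[2L], pars[3L])
    A_def <- polygon_area(hensen_loop(geom, st))
    expect_equal(A_def, A_ref, tolerance = 1e-5,
                 label = sprintf("Hensen area at eps=%g", pars[1L]))
    # fluid area conservation on the same solves
    expect_equal(st$fluid$A_SN + st$fluid$A_OT, geom$A_SN0 + geom$A_OT0,
                 tolerance = 1e-5)
  }
})

test_that("enclosed-area conservation is translation invariant", {
  cfg <- cortikin:::canonical_config(default_fixture())
  shift <- c(-40, 13)
  for (f in c("pivot_rl", "dc_anchor", "outer_pillar_foot", "inner_pillar_foot")) {
    cfg[[f]] <- cfg[[f]] + shift
  }
  cfg$hensen_control_points <- sweep(cfg$hensen_control_points, 2L, shift, "+")
  cfg$hensen_coeffs <- bezier_to_poly(cfg$hensen_control_points)
  gt <- build_reference_geometry(cfg)
  st <- solve_deformation(gt, 0.005, 1.15, 0.1)
  expect_equal(polygon_area(hensen_loop(gt, st)), gt$A_HC0, tolerance = 1e-5)
  # and the observables agree with the untranslated geometry
  ob0 <- observables(fitted_state())
  obt <- observables(st)
  expect_equal(obt$d_rl, ob0$d_rl, tolerance = 1e-6)
  expect_equal(obt$hensen_top_vertical, ob0$hensen_top_vertical, tolerance = 1e-5)
})

test_that("the elastica returns the reference identically at eps = 0", {
  geom <- test_geometry()
  fs0 <- solve_fluid_space(geom, 0, 1.15)
  ct <- solve_hensen_contour(geom, fs0, 0, 0.1)
  tab <- cortikin:::contour_table(geom)
  expect_equal(ct$phi_nodes, tab$phi0, tolerance = 1e-12)
  expect_lt(ct$energy, 1e-12)
  expect_lt(max(abs(ct$multipliers)), 1e-9)
})

test_that("solved contours are stationary points of the discrete Lagrangian", {
  geom <- test_geometry()
  st <- fitted_state()
  ct <- st$contour
  tab <- cortikin:::contour_table(geom)
  N <- ct$n_nodes
  z <- c(ct$phi_nodes, ct$multipliers)
  lagr <- function(z) {
    phi <- z[1:(N + 1L)]; lam <- z[(N + 2L):(N + 6L)]
    xy <- cortikin:::contour_coords(phi, ct$ds, tab$anchor)
    S <- cortikin:::polyline_ydx(xy)
    discrete_curvature_energy(phi, tab$phi0, ct$gamma_eps, ct$ds) +
      lam[1L] * (xy[N + 1L, 1L] - st$fluid$ohc_apex[1L]) +
      lam[2L] * (xy[N + 1L, 2L] - st$fluid$ohc_apex[2L]) +
      lam[3L] * (S - ct$c_area) +
      lam[4L] * ((phi[2L] - phi[1L]) / ct$ds - ct$gamma_eps * tab$kappa0_start) +
      lam[5L] * (phi[N + 1L] - ct$phi_e)
  }
  # central finite-difference gradient of the Lagrangian at the solution
  h <- 1e-6
  grad <- vapply(seq_along(z), function(j) {
    zp <- z; zm <- z
    zp[j] <- zp[j] + h; zm[j] <- zm[j] - h
    (lagr(zp) - lagr(zm)) / (2 * h)
  }, numeric(1L))
  expect_lt(max(abs(grad)), 1e-6)
})

test_that("contour constraints hold by construction at the fitted parameters", {
  geom <- test_geometry()
  st <- fitted_state()
  ct <- st$contour
  expect_equal(ct$arc_length, (1 + 0.005 * 0.1) * ct$L0, tolerance = 1e-12)
  # apex endpoint matches the fluid apex
  expect_lt(sqrt(sum((ct$coords[ct$n_nodes + 1L, ] - st$fluid$ohc_apex)^2)),
            1e-6)
  # boundary angle: deformed arc tangent plus the constant reference offset
  tab <- cortikin:::contour_table(geom)
  expect_equal(ct$phi_nodes[ct$n_nodes + 1L],
               cortikin:::arc_tangent_at_apex(st$fluid$ohc_apex, st$fluid$ohc_base,
                                              geom$a_arc, st$fluid$phi) +
                 tab$phie_off,
               tolerance = 1e-9)
})

test_that("material points interpolate the deformed contour correctly", {
  geom <- test_geometry()
  st0 <- solve_deformation(geom, 0, 1.15, 0.1)
  L0 <- st0$contour$L0
  # fixed anchor at s0 = 0; apex at s0 = L0; identity at eps = 0
  expect_equal(material_point(st0$contour, 0), geom$hensen_anchor,
               tolerance = 1e-12)
  expect_equal(material_point(st0$contour, L0), geom$ohc_apex_0,
               tolerance = 1e-9)
  mid_ref <- cortikin:::reference_point(geom, 0.5 * L0)
  expect_equal(material_point(st0$contour, 0.5 * L0), mid_ref,
               tolerance = 1e-12)
  st <- fitted_state()
  expect_equal(material_point(st$contour, 0), geom$hensen_anchor,
               tolerance = 1e-12)
  expect_equal(material_point(st$contour, L0), st$fluid$ohc_apex,
               tolerance = 1e-6)
  expect_error(material_point(st$contour, -1), "s0_reference")
})

test_that("tracked displacements are grid-converged at N = 100", {
  geom <- test_geometry()
  o1 <- observables(fitted_state())
  o2 <- observables(solve_deformation(geom, 0.005, 1.15, 0.1,
                                      oc_control(n_nodes = 200L)))
  d1 <- c(o1$hensen_top_radial, o1$hensen_top_vertical)
  d2 <- c(o2$hensen_top_radial, o2$hensen_top_vertical)
  expect_lt(sqrt(sum((d1 - d2)^2)) / sqrt(sum(d2^2)), 0.01)
  s1 <- c(o1$hensen_side_radial, o1$hensen_side_vertical)
  s2 <- c(o2$hensen_side_radial, o2$hensen_side_vertical)
  expect_lt(sqrt(sum((s1 - s2)^2)) / sqrt(sum(s2^2)), 0.01)
})

test_that("admissible perturbations do not lower the constrained energy", {
  geom <- test_geometry()
  st <- fitted_state()
  ct <- st$contour
  tab <- cortikin:::contour_table(geom)
  N <- ct$n_nodes
  phi <- ct$phi_nodes
  # constraint gradients (rows) at the solution, by finite differences
  cons <- function(phi) {
    xy <- cortikin:::contour_coords(phi, ct$ds)
    c(xy[N + 1L, 1L], xy[N + 1L, 2L], cortikin:::polyline_ydx(xy),
      (phi[2L] - phi[1L]) / ct$ds, phi[N + 1L])
  }
  h <- 1e-6
  Jc <- vapply(seq_len(N + 1L), function(j) {
    pp <- phi; pm <- phi
    pp[j] <- pp[j] + h; pm[j] <- pm[j] - h
    (cons(pp) - cons(pm)) / (2 * h)
  }, numeric(5L))
  set.seed(21)
  E0 <- ct$energy
  for (k in 1:8) {
    d <- rnorm(N + 1L)
    # project onto the tangent space of the constraints
    d <- d - t(Jc) %*% solve(Jc %*% t(Jc), Jc %*% d)
    d <- 1e-4 * d / sqrt(sum(d^2))
    E1 <- discrete_curvature_energy(phi + as.numeric(d), tab$phi0,
                                    ct$gamma_eps, ct$ds)
    expect_gt(E1 - E0, -1e-10)
  }
})
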