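test_that("the critical extensibility is a verified root of D_RL", {
  geom <- test_geometry()
  dc <- critical_extensibility(geom)
  # root property
  expect_lt(abs(attr(dc, "d_rl")), 1e-6)
  fs <- solve_fluid_space(geom, 0.005, as.numeric(dc))
  expect_lt(abs(sum((fs$ohc_apex - geom$ohc_apex_0) * geom$bm_normal)), 1e-6)

  # grid-scan oracle: the 0.001-step sign change brackets the bisection root
  grid <- seq(1.1, 1.3, by = 0.001)
  drl <- vapply(grid, function(D) {
    fs <- solve_fluid_space(geom, 0.005, D)
    sum((fs$ohc_apex - geom$ohc_apex_0) * geom$bm_normal)
  }, numeric(1L))
  flip <- which(diff(sign(drl)) != 0)[1L]
  expect_gte(as.numeric(dc), grid[flip])
  expect_lte(as.numeric(dc), grid[flip + 1L])

  # Delta_C varies only slightly with the probe contraction
  d1 <- critical_extensibility(geom, epsilon = 0.002)
  d2 <- critical_extensibility(geom, epsilon = 0.01)
  expect_lt(abs(as.numeric(d1) - as.numeric(d2)), 0.1)

  expect_error(critical_extensibility(geom, epsilon = 0), "nonzero")
})

test_that("the operating-point gain is monotone and matches a local fit", {
  geom <- test_geometry()
  eps0 <- seq(-0.02, 0.02, by = 0.005)
  gains <- vapply(eps0, function(e) rl_gain(geom, 1.15, 0.1, e), numeric(1L))
  expect_true(all(diff(gains) < 0))      # monotone decreasing in eps0

  # central difference agrees with the slope of a local quadratic fit
  e0 <- 0.01
  pts <- e0 + c(-2, -1, 0, 1, 2) * 1e-3
  d <- vapply(pts, function(e) {
    fs <- solve_fluid_space(geom, e, 1.15)
    sum((fs$ohc_apex - geom$ohc_apex_0) * geom$bm_normal)
  }, numeric(1L))
  fit <- lm(d ~ poly(pts, 2, raw = TRUE))
  slope <- coef(fit)[2L] + 2 * coef(fit)[3L] * e0
  expect_equal(rl_gain(geom, 1.15, 0.1, e0), as.numeric(slope),
               tolerance = 1e-3)
})

test_that("oscillatory response is linear in the drive and operating-point set", {
  geom <- test_geometry()
  r1 <- oscillatory_response(geom, eps0 = 0.01, eps_osc = 0.001)
  r2 <- oscillatory_response(geom, eps0 = 0.01, eps_osc = 0.002)
  expect_identical(r2$d_rl_osc, 2 * r1$d_rl_osc)

  # elongated operating point: virtually no reticular-lamina oscillation
  relax <- oscillatory_response(geom, eps0 = -0.02, eps_osc = 0.001)
  expect_lt(relax$d_rl_osc, 0.001)

  # linearisation vs full nonlinear solves, within 5%
  full <- (cortikin:::d_rl_fluid(geom, 0.01 + 0.001, 1.15) -
             cortikin:::d_rl_fluid(geom, 0.01 - 0.001, 1.15)) / 2
  expect_equal(r1$d_rl_osc, abs(full), tolerance = 0.05)

  expect_error(oscillatory_response(geom, eps0 = 0.03), "eps0")
  expect_error(oscillatory_response(geom, eps_osc = 0.01), "eps_osc")
})

test_that("contraction sweeps flag failures and show the plateau asymmetry", {
  geom <- test_geometry()
  # single-point grid at zero: exact zero row
  sw0 <- sweep_contraction(geom, eps_grid = 0)
  expect_true(sw0$converged)
  expect_lt(abs(sw0$d_rl), 1e-9)

  sw <- sweep_contraction(geom, 1.15, 0.1, eps_grid = seq(-0.02, 0.02, by = 0.005))
  expect_true(all(sw$converged))
  # displacements plateau for elongation but keep growing under contraction
  d <- setNames(sw$d_rl, as.character(sw$epsilon))
  expect_lt(abs(d[["-0.02"]] - d[["-0.01"]]),
            abs(d[["0.02"]] - d[["0.01"]]) / 3)
  # Hensen motion keeps growing upon contraction, opposite in sign to D_RL
  ht <- setNames(sw$hensen_top_vertical, as.character(sw$epsilon))
  expect_true(all(diff(ht[as.character(seq(0, 0.02, by = 0.005))]) > 0))
  expect_true(all(sign(ht[sw$epsilon != 0]) == -sign(d[sw$epsilon != 0])))
  # D_RL decreases with contraction away from the elongation plateau
  dec <- d[as.character(seq(-0.01, 0.02, by = 0.005))]
  expect_true(all(diff(dec) < 0))

  # an unsolvable direction is flagged, not an error, and the sweep continues
  sw2 <- sweep_contraction(geom, 2.5, 0.01, eps_grid = seq(-0.02, 0.02, by = 0.01))
  expect_false(all(sw2$converged))
  expect_true(any(sw2$converged))
  expect_true(all(is.na(sw2$d_rl[!sw2$converged])))
})

test_that("region classification finds the realistic parameter neighbourhood", {
  geom <- test_geometry()
  region <- classify_parameter_region(geom, delta_grid = c(0.8, 1.15, 1.5),
                                      gamma_grid = c(0.1, 0.3))
  fitted <- region[region$delta == 1.15 & region$gamma == 0.1, ]
  expect_true(fitted$solvable)
  expect_true(fitted$realistic)
  # above the critical Delta the RL moves the wrong way: not realistic
  high <- region[region$delta == 1.5 & region$gamma == 0.1, ]
  expect_gt(high$d_rl, 0)
  expect_false(high$realistic)
  # large Gamma flips the top point's radial direction: not realistic
  wide <- region[region$delta == 1.15 & region$gamma == 0.3, ]
  expect_gt(wide$hensen_top_radial, 0)
  expect_false(wide$realistic)
})

test_that("region classification is stable under a different continuation step", {
  geom <- test_geometry()
  r1 <- classify_parameter_region(geom, 1.15, c(0.05, 0.1), eps_max = 0.01)
  r2 <- classify_parameter_region(geom, 1.15, c(0.05, 0.1), eps_max = 0.01,
                                  control = oc_control(continuation_step = 5e-4))
  expect_identical(r1$solvable, r2$solvable)
  expect_identical(sign(r1$hensen_top_radial), sign(r2$hensen_top_radial))
  expect_identical(r1$realistic, r2$realistic)
})
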