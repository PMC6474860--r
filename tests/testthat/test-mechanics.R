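test_that("pressure unit conversion matches the printed pairs", {
  expect_equal(mmhg_to_kpa(0), 0)
  expect_equal(mmhg_to_kpa(10.5), 1.4, tolerance = 0.01)
  expect_equal(mmhg_to_kpa(15.8), 2.107, tolerance = 0.001)
})

test_that("thin-shell stress follows Laplace's law", {
  expect_equal(circumferential_stress(0, 8.4, 1000), 0)
  expect_equal(circumferential_stress(15, 8.373, 980), 8.54, tolerance = 1e-3)
  # doubling thickness halves stress; stress is linear in pressure
  s1 <- circumferential_stress(15, 8.373, 980)
  expect_equal(circumferential_stress(15, 8.373, 1960), s1 / 2)
  expect_equal(circumferential_stress(30, 8.373, 980), 2 * s1)
  expect_error(circumferential_stress(15, 8.373, 0), "T_um")
  expect_error(circumferential_stress(15, -1, 980), "R_mm")
})

test_that("volumetric strain is positive under inflation", {
  expect_equal(volumetric_strain(100, 100), 0)
  expect_equal(volumetric_strain(100, 105), 0.05)
  v_ref <- cap_volume(3.0, 5.25)
  v <- cap_volume(cap_height(3.0, 143, 52), 5.25)
  expect_equal(volumetric_strain(v_ref, v), 3.195 / 3 - 1, tolerance = 1e-12)
  expect_error(volumetric_strain(0, 1), "V_ref")
})

test_that("tangent modulus carries the 3(1 - v) thin-shell coefficient", {
  expect_equal(tangent_modulus(1, 1, v = 0.4), 1.8)
  expect_equal(tangent_modulus(8.54, 0.0768, v = 0.4), 200.2, tolerance = 1e-3)
  # linear in stress at fixed strain
  expect_equal(tangent_modulus(17.08, 0.0768), 2 * tangent_modulus(8.54, 0.0768))
  expect_error(tangent_modulus(1, 0), "reference")
  expect_error(tangent_modulus(1, 0.1, v = 0.6), "v")
})

test_that("build_curves anchors strain at the 2 mmHg loading state", {
  series <- simulate_geometry(pressure_schedule(), forward_params())
  curves <- build_curves(series)
  ref <- curves[curves$phase == "loading" & curves$P_mmHg == 2, ]
  expect_equal(ref$epsilon, 0)
  expect_true(is.na(ref$E_kPa)) # no modulus point at the reference
  expect_false(any(curves$P_mmHg < 2)) # sub-reference steps excluded
  load <- curves[curves$phase == "loading" & curves$P_mmHg > 2, ]
  expect_true(all(load$E_kPa > 0))
  # the secant-type modulus diverges toward the reference; away from it the
  # curve rises with pressure, approximately linearly above 20 mmHg
  mid <- load[load$P_mmHg >= 10, ]
  expect_true(all(diff(mid$E_kPa) > 0))
  hi <- load[load$P_mmHg >= 20, ]
  r2 <- summary(lm(E_kPa ~ P_mmHg, data = hi))$r.squared
  expect_gt(r2, 0.98)

  no_ref <- series[!(series$phase == "loading" & series$P_mmHg == 2), ]
  expect_error(build_curves(no_ref), "reference")
})

test_that("loop area: zero for identical curves, exact for rectangles, symmetric", {
  l <- tibble::tibble(epsilon = c(0, 0.05, 0.1), sigma_kPa = c(1, 2, 4))
  expect_equal(hysteresis_area(l, l)$hysteresis_kPa, 0)

  # parallel lines 1 kPa apart over a strain span of 0.1 -> 0.1 kPa
  u <- l
  u$sigma_kPa <- l$sigma_kPa - 1
  out <- hysteresis_area(l, u)
  expect_equal(out$hysteresis_kPa, 0.1, tolerance = 1e-12)
  expect_equal(out$hysteresis_mmHg, 0.1 / 0.1333224, tolerance = 1e-12)

  # symmetric in its arguments, invariant to point order
  expect_equal(hysteresis_area(u, l), out)
  expect_equal(hysteresis_area(l[3:1, ], u[c(2, 1, 3), ]), out)

  disjoint <- tibble::tibble(epsilon = c(0.2, 0.3), sigma_kPa = c(1, 2))
  expect_error(hysteresis_area(l, disjoint), "disjoint")
})

test_that("loop area matches the shoelace polygon oracle on piecewise-linear loops", {
  withr::with_seed(4, {
    for (i in 1:25) {
      # knots at quarters of the strain span so the 513-point grid is exact;
      # the unloading curve is kept strictly below loading (no crossings)
      span <- runif(1, 0.02, 0.2)
      eps <- seq(0, span, length.out = 5)
      sig_l <- cumsum(runif(5, 0.5, 3))
      gap <- runif(5, 0.2, 1.5)
      l <- tibble::tibble(epsilon = eps, sigma_kPa = sig_l)
      u <- tibble::tibble(epsilon = eps, sigma_kPa = sig_l - gap)
      got <- hysteresis_area(l, u, n_grid = 513)$hysteresis_kPa
      want <- shoelace_loop_area(l, u)
      expect_equal(got, want, tolerance = 1e-9)
    }
  })
})

test_that("trapezoidal loop area converges under grid refinement", {
  series <- simulate_geometry(pressure_schedule(), forward_params())
  curves <- build_curves(series)
  a1 <- hysteresis(curves, n_grid = 512)$hysteresis_kPa
  a2 <- hysteresis(curves, n_grid = 1024)$hysteresis_kPa
  expect_lt(abs(a2 - a1) / a1, 1e-3)
})

test_that("mechanics summary reports the loading modulus and loop area per hour", {
  series <- simulate_geometry(pressure_schedule(hours = c(0, 1)), forward_params())
  curves <- build_curves(series)
  sm <- mechanics_summary(curves)
  expect_equal(sm$hour, c(0, 1))
  expect_equal(sm$E_loading_kPa[1], modulus_at(curves, 15, "loading", 0))
  expect_equal(sm$hysteresis_kPa, hysteresis(curves)$hysteresis_kPa)
  expect_equal(glance(curves), sm)
})
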