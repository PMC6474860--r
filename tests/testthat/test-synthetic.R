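test_that("loading-phase geometry laws reproduce their closed forms", {
  p <- forward_params()
  s <- simulate_geometry(pressure_schedule(), p)
  load <- s[s$phase == "loading", ]

  expect_equal(load$T_um[load$P_mmHg == 0], 1085.5)
  expect_equal(load$T_um[load$P_mmHg == 60], 1085.5 - 57.3 * 60^0.265,
               tolerance = 1e-12)
  expect_equal(load$T_um[load$P_mmHg == 60], 915.9, tolerance = 1e-4)
  expect_equal(load$R_mm[load$P_mmHg == 60], 8.148, tolerance = 1e-12)
  # default displacement amplitude anchors the 2 -> 60 mmHg gain at 143 um
  expect_equal(load$D_um[load$P_mmHg == 60] - load$D_um[load$P_mmHg == 2], 143,
               tolerance = 1e-9)
})

test_that("zero pressure lag closes the loop; positive lag opens it", {
  sched <- pressure_schedule()
  s0 <- simulate_geometry(sched, forward_params(lam = 0))
  wide <- merge(
    s0[s0$phase == "loading", c("P_mmHg", "T_um", "D_um", "R_mm")],
    s0[s0$phase == "unloading", c("P_mmHg", "T_um", "D_um", "R_mm")],
    by = "P_mmHg"
  )
  expect_equal(wide$T_um.x, wide$T_um.y)
  expect_equal(wide$D_um.x, wide$D_um.y)

  s1 <- simulate_geometry(sched, forward_params(lam = 0.25))
  un <- s1[s1$phase == "unloading" & s1$P_mmHg > 0, ]
  lo <- s1[s1$phase == "loading", ]
  lo <- lo[match(un$P_mmHg, lo$P_mmHg), ]
  expect_true(all(un$T_um < lo$T_um))
  expect_true(all(un$D_um > lo$D_um))
  # the radius law is shared between phases
  expect_equal(un$R_mm, lo$R_mm)
})

test_that("simulated loading thickness strictly decreases and displacement strictly increases in P", {
  s <- simulate_geometry(pressure_schedule(unloading = FALSE), forward_params())
  s <- s[s$P_mmHg > 0, ]
  expect_true(all(diff(s$T_um) < 0))
  expect_true(all(diff(s$D_um) > 0))
})

test_that("swelling factor hits its anchors and saturates monotonically", {
  p <- forward_params()
  expect_equal(swelling_factor(0, p), 1)
  expect_equal(swelling_factor(1, p), 1.06, tolerance = 1e-9)
  # the plateau is solved so hour-4 zero-pressure thickness is 1222.47 um
  expect_equal(swelling_factor(4, p) * p$a, 1222.47, tolerance = 1e-6)
  h <- seq(0, 24, by = 0.25)
  sh <- swelling_factor(h, p)
  expect_true(all(diff(sh) >= 0))
  expect_true(all(sh <= p$swell_sinf + 1e-12))
  expect_error(swelling_factor(-1, p), "hour")
})

test_that("degenerate forward-model inputs are rejected", {
  expect_error(simulate_geometry(pressure_schedule(), forward_params(b = 5000)),
               "non-positive thickness")
  expect_error(pressure_schedule(hours = -1), ">= 0")
  expect_error(forward_params(c = 1.5), "0, 1")
  expect_error(forward_params(H2 = 0), "H2")
  sched <- pressure_schedule()
  sched$P_mmHg[3] <- 70 # breaks loading monotonicity
  expect_error(simulate_geometry(sched, forward_params()), "monotone")
})

test_that("cap height update combines displacement and thinning per hour", {
  p <- forward_params()
  s <- simulate_geometry(pressure_schedule(hours = c(0, 2)), p)
  for (h in c(0, 2)) {
    g <- s[s$hour == h, ]
    ref <- g[g$phase == "loading" & g$P_mmHg == 2, ]
    expect_equal(
      g$H_mm,
      p$H2 + (g$D_um - ref$D_um) / 1000 + (ref$T_um - g$T_um) / 1000
    )
  }
})

test_that("rendered B-scans are deterministic and geometrically faithful", {
  p <- forward_params()
  st <- simulate_geometry(pressure_schedule(), p)[4, ] # 10 mmHg loading
  opt <- small_optics(speckle_sigma = 0.3)
  b1 <- render_bscan(st, opt, seed = 7)
  b2 <- render_bscan(st, opt, seed = 7)
  expect_identical(b1$pixels, b2$pixels)
  b3 <- render_bscan(st, opt, seed = 8)
  expect_false(identical(b1$pixels, b3$pixels))

  # noiseless: per-column argmax of the anterior edge gradient within 1 px
  opt0 <- small_optics(speckle_sigma = 0)
  b <- render_bscan(st, opt0)
  img <- b$pixels
  g <- img[-1, ] - img[-nrow(img), ] # signed: the anterior edge is the
  est <- apply(g, 2, which.max) * opt0$axial_um_per_px # strongest rise
  tr <- detect_surfaces(b)
  truth <- true_anterior_um(st, tr, opt0)
  expect_lt(max(abs(est - truth)), 1.5 * opt0$axial_um_per_px)

  # as-imaged apex gap equals n_group * T within one pixel
  apex_col <- which.min(truth)
  col <- img[, apex_col]
  dif <- diff(col)
  a_idx <- which.max(dif)
  p_idx <- which.min(dif)
  gap_px <- p_idx - a_idx
  expect_lt(abs(gap_px - opt0$n_group * st$T_um / opt0$axial_um_per_px), 1.5)
})

test_that("surfaces outside the axial field raise a field-of-view error", {
  st <- simulate_geometry(pressure_schedule(), forward_params())[1, ]
  expect_error(render_bscan(st, small_optics(axial_fov_um = 1500)),
               "field-of-view")
  expect_error(optics_config(lateral_fov_mm = 4), "6")
  expect_error(optics_config(axial_um_per_px = 5), "PSF")
})

test_that("modulus calibration hits its target and validates input", {
  expect_error(calibrate_to_modulus(-5), "positive")
  p <- calibrate_to_modulus(198.25)
  e <- octinflate:::analytic_e15(p)
  expect_lt(abs(e - 198.25) / 198.25, 1e-3)
  p2 <- calibrate_to_modulus(315.84)
  expect_lt(abs(octinflate:::analytic_e15(p2) - 315.84) / 315.84, 1e-3)
  # more compliant target -> larger displacement amplitude
  expect_gt(p$Dmax, p2$Dmax)
})

test_that("displacement-gain calibration is exact for the exponential law", {
  p <- calibrate_dmax_to_displacement(143)
  s <- simulate_geometry(pressure_schedule(unloading = FALSE), p)
  expect_equal(s$D_um[s$P_mmHg == 60] - s$D_um[s$P_mmHg == 2], 143,
               tolerance = 1e-9)
})

test_that("lag calibration reaches feasible loop areas and reports its ceiling", {
  p <- calibrate_lam_to_hysteresis(2.5)
  s <- simulate_geometry(pressure_schedule(), p)
  h <- hysteresis(build_curves(s, B = p$B))
  expect_lt(abs(h$hysteresis_mmHg - 2.5) / 2.5, 2e-3)
  expect_error(calibrate_lam_to_hysteresis(50), "achievable")
})
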