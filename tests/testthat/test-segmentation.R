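load_state <- function(P = 15, hour = 0) {
  s <- simulate_geometry(pressure_schedule(hours = hour), forward_params())
  s[s$P_mmHg == P & s$phase == "loading" & s$hour == hour, ]
}

test_that("noiseless segmentation tracks both surfaces within one axial pixel", {
  st <- load_state(15)
  opt <- small_optics(speckle_sigma = 0)
  b <- render_bscan(st, opt)
  tr <- detect_surfaces(b)
  truth_a <- true_anterior_um(st, tr, opt)
  truth_p <- truth_a + opt$n_group * st$T_um
  core <- 6:(nrow(tr) - 5) # median-filter end rule distorts the outermost columns
  expect_lt(max(abs(tr$anterior_um - truth_a)[core]), opt$axial_um_per_px)
  expect_lt(max(abs(tr$posterior_um - truth_p)[core]), opt$axial_um_per_px)
})

test_that("default-speckle segmentation stays within 2 axial pixels RMS", {
  st <- load_state(15)
  opt <- small_optics(speckle_sigma = 0.3, seed = 42L)
  b <- render_bscan(st, opt)
  tr <- detect_surfaces(b)
  truth_a <- true_anterior_um(st, tr, opt)
  core <- 6:(nrow(tr) - 5)
  rms_px <- sqrt(mean((tr$anterior_um - truth_a)[core]^2)) / opt$axial_um_per_px
  expect_lt(rms_px, 2)
})

test_that("featureless images raise a segmentation-failure error", {
  b <- structure(
    list(pixels = matrix(0.3, 400, 200), axial_um_per_px = 3,
         lateral_um_per_px = 20, n_group = 1.389),
    class = "bscan"
  )
  expect_error(detect_surfaces(b), "segmentation failure")
  b$pixels <- matrix(0.3, 50, 50)
  expect_error(detect_surfaces(b), "100 x 100")
})

test_that("segmentation is deterministic and translation-equivariant", {
  st <- load_state(10)
  opt <- small_optics(speckle_sigma = 0.3, seed = 11L)
  b <- render_bscan(st, opt)
  t1 <- detect_surfaces(b)
  t2 <- detect_surfaces(b)
  expect_identical(t1$anterior_um, t2$anterior_um)

  # shift the image k axial pixels: both traces shift by exactly k
  k <- 25L
  nr <- nrow(b$pixels)
  shifted <- b
  shifted$pixels <- rbind(
    matrix(b$pixels[1, ], k, ncol(b$pixels), byrow = TRUE),
    b$pixels[1:(nr - k), ]
  )
  t3 <- detect_surfaces(shifted)
  dz <- k * opt$axial_um_per_px
  expect_equal(t3$anterior_um, t1$anterior_um + dz, tolerance = 1e-8)
  expect_equal(t3$posterior_um, t1$posterior_um + dz, tolerance = 1e-8)
})

test_that("refraction correction divides the optical gap by the group index", {
  tr <- make_traces(
    x_um = seq(20, 4000, by = 20),
    anterior_um = rep(500, 200),
    posterior_um = rep(500 + 1389, 200),
    depths = "optical", n_group = 1.389
  )
  out <- correct_refraction(tr, 1.389)
  expect_equal(out$posterior_um - out$anterior_um, rep(1000, 200))
  expect_equal(out$anterior_um, tr$anterior_um) # air path untouched

  # linearity: doubling the optical gap doubles the physical gap
  tr2 <- tr
  tr2$posterior_um <- tr$anterior_um + 2 * (tr$posterior_um - tr$anterior_um)
  out2 <- correct_refraction(tr2, 1.389)
  expect_equal(out2$posterior_um - out2$anterior_um,
               2 * (out$posterior_um - out$anterior_um))

  # n = 1 is the identity; indices below 1 are rejected
  out_id <- correct_refraction(tr, 1)
  expect_equal(out_id$posterior_um, tr$posterior_um)
  expect_error(correct_refraction(tr, 0.9), "n_group")
  expect_error(correct_refraction(out, 1.389), "already")
})

test_that("full noiseless round trip recovers the generator geometry", {
  sched <- pressure_schedule(unloading = FALSE)
  p <- forward_params()
  truth <- simulate_geometry(sched, p)
  keep <- truth$P_mmHg %in% c(2, 15, 60)
  opt <- small_optics(speckle_sigma = 0)
  stack <- render_stack(truth[keep, ], opt)
  meas <- extract_geometry(stack, sched[keep, ], H2 = p$H2)
  tt <- truth[keep, ]
  # thickness within the stated 2.2 um repeatability, radius within 1 %
  expect_lt(max(abs(meas$T_um - tt$T_um)), 2.2)
  expect_lt(max(abs(meas$R_mm - tt$R_mm) / tt$R_mm), 0.01)
  # displacement relative to the 2 mmHg reference within one axial pixel
  dd_true <- tt$D_um - tt$D_um[tt$P_mmHg == 2]
  expect_lt(max(abs(meas$D_um - dd_true)), opt$axial_um_per_px)
})
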