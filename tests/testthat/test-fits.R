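loading_pressures <- c(0, 2, seq(5, 60, 5))

test_that("noiseless thickness data recover the power-law coefficients", {
  d <- tibble::tibble(
    P_mmHg = loading_pressures,
    T_um = 1085.5 - 57.3 * loading_pressures^0.265
  )
  fit <- fit_thickness_power(d)
  expect_equal(fit$params$a, 1085.5, tolerance = 1e-6 / 1085.5)
  expect_equal(fit$params$b, 57.3, tolerance = 1e-6)
  expect_equal(fit$params$c, 0.265, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)

  expect_error(fit_thickness_power(d[1:3, ]), "4 points")
  expect_error(fit_thickness_power(d[c(1, 2, 2, 1), ]), "distinct positive")
})

test_that("constant thickness yields b = 0 with the exponent flagged", {
  d <- tibble::tibble(P_mmHg = c(0, 2, 5, 10, 20), T_um = rep(1000, 5))
  fit <- fit_thickness_power(d)
  expect_equal(fit$params$a, 1000)
  expect_equal(fit$params$b, 0)
  expect_true("c" %in% fit$unidentifiable)
  td <- tidy(fit)
  expect_true(td$unidentifiable[td$term == "c"])
})

test_that("noisy thickness recovery is unbiased across seeds", {
  cs <- withr::with_seed(2024, {
    vapply(1:100, function(i) {
      d <- tibble::tibble(
        P_mmHg = loading_pressures,
        T_um = 1085.5 - 57.3 * loading_pressures^0.265 + rnorm(14, sd = 2)
      )
      fit_thickness_power(d)$params$c
    }, numeric(1))
  })
  expect_lt(abs(mean(cs) - 0.265), 0.02)
})

test_that("radius fits are exact on linear data and near-unbiased under noise", {
  P <- loading_pressures[loading_pressures >= 2]
  d <- tibble::tibble(P_mmHg = P, R_mm = 8.448 - 0.005 * P)
  fit <- fit_radius_linear(d)
  expect_equal(fit$params$intercept, 8.448, tolerance = 1e-9)
  expect_equal(fit$params$slope, -0.005, tolerance = 1e-9)

  # two points: the exact interpolating line
  two <- fit_radius_linear(tibble::tibble(P_mmHg = c(10, 30), R_mm = c(8.0, 7.6)))
  expect_equal(two$params$intercept, 8.2, tolerance = 1e-12)
  expect_equal(two$params$slope, -0.02, tolerance = 1e-12)
  expect_error(fit_radius_linear(tibble::tibble(P_mmHg = c(5, 5), R_mm = c(1, 2))),
               "distinct")

  # residuals at the optimum are orthogonal to the design columns
  dn <- withr::with_seed(5, {
    tibble::tibble(P_mmHg = P, R_mm = 8.448 - 0.005 * P + rnorm(length(P), sd = 0.02))
  })
  fn <- fit_radius_linear(dn)
  expect_lt(abs(sum(fn$residuals)), 1e-9)
  expect_lt(abs(sum(fn$residuals * P)), 1e-7)

  ints <- withr::with_seed(7, {
    vapply(1:100, function(i) {
      dd <- tibble::tibble(P_mmHg = P, R_mm = 8.448 - 0.005 * P + rnorm(length(P), sd = 0.02))
      fit_radius_linear(dd)$params$intercept
    }, numeric(1))
  })
  expect_lt(abs(mean(ints) - 8.448) / 8.448, 0.005)
})

test_that("displacement fits recover the exponential law and its degenerate case", {
  P <- loading_pressures
  d <- tibble::tibble(P_mmHg = P, D_um = 150 * (1 - exp(-P / 12)))
  fit <- fit_displacement_exponential(d)
  expect_equal(fit$params$Dmax, 150, tolerance = 1e-6 / 150)
  expect_equal(fit$params$Pc, 12, tolerance = 1e-6 / 12)

  z <- fit_displacement_exponential(tibble::tibble(P_mmHg = c(0, 5, 10), D_um = 0))
  expect_equal(z$params$Dmax, 0)
  expect_true("Pc" %in% z$unidentifiable)
  expect_error(fit_displacement_exponential(d[1:2, ]), "3 points")

  # generator defaults: fitted displacement gain over the cycle is 143 um
  s <- simulate_geometry(pressure_schedule(unloading = FALSE), forward_params())
  fd <- fit_displacement_exponential(s)
  gain <- with(fd$params, Dmax * (exp(-2 / Pc) - exp(-60 / Pc)))
  expect_equal(gain, 143, tolerance = 1e-6)
})

test_that("fits are deterministic and expose broom-style accessors", {
  d <- withr::with_seed(9, {
    tibble::tibble(
      P_mmHg = loading_pressures,
      T_um = 1085.5 - 57.3 * loading_pressures^0.265 + rnorm(14, sd = 2)
    )
  })
  f1 <- fit_thickness_power(d)
  f2 <- fit_thickness_power(d)
  expect_identical(tidy(f1), tidy(f2))
  g <- glance(f1)
  expect_named(g, c("rss", "n", "converged", "n_unidentifiable"))
  expect_equal(g$n, 14)
  expect_true(g$converged)
})
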