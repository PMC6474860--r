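#' Convert mmHg to kPa
#'
#' @param x Pressure(s) in mmHg.
#' @param factor kPa per mmHg.
#' @return Pressure(s) in kPa.
#' @export
#' @examples
#' mmhg_to_kpa(10.5) # ~ 1.4 kPa
mmhg_to_kpa <- function(x, factor = 0.1333224) x * factor

#' Thin-walled-sphere circumferential stress
#'
#' Laplace-law hoop stress `sigma = P * R / (2 * T)` for a thin spherical
#' shell, with the pressure converted to kPa and the thickness to mm.
#'
#' @param P_mmHg Internal pressure (mmHg, >= 0).
#' @param R_mm Radius of curvature of the anterior apex (mm, > 0).
#' @param T_um Apex thickness (um, > 0).
#' @return Stress in kPa.
#' @export
#' @examples
#' circumferential_stress(15, 8.373, 980) # ~ 8.54 kPa
circumferential_stress <- function(P_mmHg, R_mm, T_um) {
  if (any(T_um <= 0)) abort("`T_um` must be positive.")
  if (any(R_mm <= 0)) abort("`R_mm` must be positive.")
  if (any(P_mmHg < 0)) abort("`P_mmHg` must be >= 0.")
  mmhg_to_kpa(P_mmHg) * R_mm / (2 * T_um / 1000)
}

#' Volumetric strain of the corneal cap
#'
#' Fractional change of the parabolic-cap volume relative to the reference
#' state, `(V - V_ref) / V_ref`, signed so that inflation (V > V_ref) gives
#' positive strain and hence a positive tangent modulus. (The literature
#' sometimes prints the opposite sign, `(V_ref - V)/V_ref`; only the sign
#' differs, not the magnitude.)
#'
#' @param V_ref Reference cap volume (mm^3, > 0), conventionally at 2 mmHg.
#' @param V Current cap volume (mm^3).
#' @return Dimensionless strain.
#' @export
volumetric_strain <- function(V_ref, V) {
  if (any(V_ref <= 0)) abort("`V_ref` must be positive.")
  (V - V_ref) / V_ref
}

#' Tangent elastic modulus of a thin spherical shell
#'
#' `E_c = 3 * (1 - v) * sigma / epsilon` for volumetric strain `epsilon`
#' and Poisson's ratio `v`.
#'
#' @param sigma Circumferential stress (kPa).
#' @param epsilon Volumetric strain (dimensionless, non-zero).
#' @param v Poisson's ratio in \[0, 0.5).
#' @return Modulus in kPa.
#' @export
#' @examples
#' tangent_modulus(8.54, 0.0768) # ~ 200 kPa
tangent_modulus <- function(sigma, epsilon, v = 0.40) {
  if (v < 0 || v >= 0.5) abort("`v` must lie in [0, 0.5).")
  if (any(epsilon == 0)) abort("modulus undefined at the reference state (epsilon = 0).")
  3 * (1 - v) * sigma / epsilon
}

#' Stress-strain curves and tangent moduli from a geometry series
#'
#' For every step at or above the reference pressure, computes the
#' thin-shell stress from that step's radius and thickness, the volumetric
#' strain of the parabolic cap relative to the reference state (loading at
#' 2 mmHg by default, per hydration hour), and the tangent modulus. The
#' reference step itself carries zero strain and no modulus; steps below
#' the reference pressure are excluded.
#'
#' @param series A `geometry_series` (simulated or measured) containing the
#'   reference step for every hour present.
#' @param config A [mechanics_config()].
#' @param B Cap base width (mm) used for volumes.
#' @return An `ss_curves` tibble: `hour`, `phase`, `P_mmHg`, `sigma_kPa`,
#'   `epsilon`, `E_kPa` (`NA` at the reference step), with the config and
#'   base width attached as attributes.
#' @export
build_curves <- function(series, config = mechanics_config(), B = 5.25) {
  req <- c("P_mmHg", "phase", "hour", "T_um", "R_mm", "D_um", "H_mm")
  miss <- setdiff(req, names(series))
  if (length(miss) > 0) {
    abort(paste0("series is missing column(s): ", paste(miss, collapse = ", ")))
  }
  out <- series |>
    as_tibble() |>
    dplyr::group_by(.data$hour) |>
    dplyr::group_modify(function(g, key) {
      ref <- which(g$phase == config$ref_phase & g$P_mmHg == config$ref_pressure)
      if (length(ref) == 0) {
        abort(sprintf(
          "missing reference step (%s at %g mmHg) for hour %g.",
          config$ref_phase, config$ref_pressure, key$hour
        ))
      }
      ref <- ref[1]
      v_ref <- cap_volume(g$H_mm[ref], B)
      g <- g[g$P_mmHg >= config$ref_pressure, ]
      eps <- volumetric_strain(v_ref, cap_volume(g$H_mm, B))
      sig <- mmhg_to_kpa(g$P_mmHg, config$mmhg_to_kpa_factor) * g$R_mm /
        (2 * g$T_um / 1000)
      tibble(
        phase = g$phase, P_mmHg = g$P_mmHg,
        sigma_kPa = sig, epsilon = eps,
        E_kPa = ifelse(eps == 0, NA_real_, 3 * (1 - config$v) * sig / eps)
      )
    }) |>
    dplyr::ungroup()
  attr(out, "config") <- config
  attr(out, "B") <- B
  class(out) <- c("ss_curves", class(out))
  out
}

#' Tangent modulus at a given pressure step
#'
#' @param curves An `ss_curves` tibble from [build_curves()].
#' @param P Pressure (mmHg).
#' @param phase `"loading"` or `"unloading"`.
#' @param hour Hydration hour.
#' @return Modulus in kPa (scalar).
#' @export
modulus_at <- function(curves, P = 15, phase = "loading", hour = 0) {
  row <- curves[curves$P_mmHg == P & curves$phase == phase & curves$hour == hour, ]
  if (nrow(row) == 0) {
    abort(sprintf("no %s step at %g mmHg (hour %g) in the curves.", phase, P, hour))
  }
  row$E_kPa[1]
}

#' Area between loading and unloading stress-strain curves
#'
#' Both curves are linearly interpolated onto a uniform strain grid over the
#' intersection of their strain ranges (no extrapolation) and the area is
#' the trapezoidal integral of `|sigma_load - sigma_unload|`. Since strain
#' is dimensionless the area has stress units; the mmHg figure is the kPa
#' area divided by the mmHg-to-kPa factor. Symmetric in its two arguments
#' and invariant to the point order within each curve.
#'
#' @param loading,unloading Data frames with columns `epsilon` and
#'   `sigma_kPa` (each >= 2 points).
#' @param n_grid Number of grid points (default 512).
#' @param factor kPa per mmHg, used for the mmHg equivalent.
#' @return One-row tibble: `hysteresis_kPa`, `hysteresis_mmHg`.
#' @export
hysteresis_area <- function(loading, unloading, n_grid = 512,
                            factor = 0.1333224) {
  for (cur in list(loading, unloading)) {
    if (!all(c("epsilon", "sigma_kPa") %in% names(cur)) || nrow(cur) < 2) {
      abort("each curve needs >= 2 points with columns `epsilon` and `sigma_kPa`.")
    }
  }
  lo <- max(min(loading$epsilon), min(unloading$epsilon))
  hi <- min(max(loading$epsilon), max(unloading$epsilon))
  if (hi <= lo) abort("the strain ranges of the two curves are disjoint.")
  grid <- seq(lo, hi, length.out = n_grid)
  sl <- approx(loading$epsilon, loading$sigma_kPa, xout = grid, ties = mean)$y
  su <- approx(unloading$epsilon, unloading$sigma_kPa, xout = grid, ties = mean)$y
  gap <- abs(sl - su)
  area <- sum((gap[-1] + gap[-n_grid]) / 2 * diff(grid))
  tibble(hysteresis_kPa = area, hysteresis_mmHg = area / factor)
}

#' Hysteresis of a stress-strain curve set
#'
#' Convenience wrapper splitting an `ss_curves` tibble into its loading and
#' unloading branches per hydration hour and integrating the loop area.
#'
#' @param curves An `ss_curves` tibble containing both phases.
#' @param n_grid Grid size passed to [hysteresis_area()].
#' @return A tibble with one row per hour: `hour`, `hysteresis_kPa`,
#'   `hysteresis_mmHg`.
#' @export
hysteresis <- function(curves, n_grid = 512) {
  factor <- attr(curves, "config")$mmhg_to_kpa_factor %||% 0.1333224
  curves |>
    as_tibble() |>
    dplyr::group_by(.data$hour) |>
    dplyr::group_modify(function(g, key) {
      l <- g[g$phase == "loading", ]
      u <- g[g$phase == "unloading", ]
      if (nrow(u) < 2) abort("curves contain no unloading branch.")
      hysteresis_area(l, u, n_grid = n_grid, factor = factor)
    }) |>
    dplyr::ungroup()
}

#' One-row-per-hour summary of a stress-strain curve set
#'
#' @param curves An `ss_curves` tibble.
#' @param P_modulus Pressure at which the loading-phase modulus is reported.
#' @return A tibble: `hour`, `E_loading_kPa` (at `P_modulus`),
#'   `hysteresis_kPa`, `hysteresis_mmHg` (NA when no unloading branch).
#' @export
mechanics_summary <- function(curves, P_modulus = 15) {
  hours <- sort(unique(curves$hour))
  purrr::map_dfr(hours, function(h) {
    g <- curves[curves$hour == h, ]
    hyst <- if (sum(g$phase == "unloading") >= 2) {
      hysteresis(g[, , drop = FALSE])
    } else {
      tibble(hour = h, hysteresis_kPa = NA_real_, hysteresis_mmHg = NA_real_)
    }
    has_p <- any(g$phase == "loading" & g$P_mmHg == P_modulus)
    tibble(
      hour = h,
      E_loading_kPa = if (has_p) {
        modulus_at(curves, P = P_modulus, phase = "loading", hour = h)
      } else {
        NA_real_
      },
      hysteresis_kPa = hyst$hysteresis_kPa[1],
      hysteresis_mmHg = hyst$hysteresis_mmHg[1]
    )
  })
}

#' @export
glance.ss_curves <- function(x, P_modulus = 15, ...) {
  mechanics_summary(x, P_modulus = P_modulus)
}
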