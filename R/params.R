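#' Build a loading/unloading pressure schedule
#'
#' The default protocol measures at 0 and 2 mmHg, then in 5 mmHg increments
#' up to `p_max` during loading, and mirrors the sequence (excluding the
#' shared peak) for unloading. The whole cycle can be repeated at several
#' hydration hours.
#'
#' @param p_max Peak pressure in mmHg (default 60).
#' @param by Pressure increment above 5 mmHg (default 5).
#' @param hours Hydration hours at which the cycle is repeated (default 0).
#' @param unloading If `FALSE`, only the loading phase is generated.
#'
#' @return A tibble with one row per step: `step`, `P_mmHg`, `phase`
#'   (`"loading"` or `"unloading"`), `hour`.
#' @export
#' @examples
#' pressure_schedule()
pressure_schedule <- function(p_max = 60, by = 5, hours = 0, unloading = TRUE) {
  if (p_max < 5) abort("`p_max` must be at least 5 mmHg.")
  if (any(hours < 0)) abort("hydration `hours` must be >= 0.")
  load_p <- c(0, 2, seq(5, p_max, by = by))
  steps <- tibble(P_mmHg = load_p, phase = "loading")
  if (unloading) {
    steps <- dplyr::bind_rows(
      steps,
      tibble(P_mmHg = rev(load_p[-length(load_p)]), phase = "unloading")
    )
  }
  out <- purrr::map_dfr(sort(as.numeric(hours)), function(h) {
    dplyr::mutate(steps, hour = h)
  }) |>
    dplyr::mutate(step = dplyr::row_number(), .before = 1)
  validate_schedule(out)
  out
}

validate_schedule <- function(schedule) {
  req <- c("P_mmHg", "phase", "hour")
  miss <- setdiff(req, names(schedule))
  if (length(miss) > 0) {
    abort(paste0("schedule is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(schedule) == 0) abort("schedule must be non-empty.")
  if (any(schedule$P_mmHg < 0)) abort("pressures must be >= 0 mmHg.")
  if (any(schedule$hour < 0)) abort("hydration hours must be >= 0.")
  if (!all(schedule$phase %in% c("loading", "unloading"))) {
    abort("phase must be 'loading' or 'unloading'.")
  }
  grp <- split(schedule, list(schedule$hour, schedule$phase), drop = TRUE)
  for (g in grp) {
    d <- diff(g$P_mmHg)
    ok <- if (g$phase[1] == "loading") all(d >= 0) else all(d <= 0)
    if (!ok) abort("pressures must be monotone within each phase.")
  }
  invisible(schedule)
}

#' Forward-model parameters for the synthetic cornea
#'
#' Parameters of the ground-truth geometry laws used by [simulate_geometry()]:
#' a shifted power law for apex thickness, `T(P) = swell(hour) * (a - b * P^c)`
#' (micrometres), a linear law for the anterior apex radius,
#' `R(P) = r0 - r1 * P` (millimetres), and a saturating exponential for apex
#' displacement, `D(P) = Dmax * (1 - exp(-P / Pc))` (micrometres). Unloading
#' states evaluate the thickness and displacement laws at the lagged pressure
#' `P * (1 + lam)`, which opens the loading/unloading loop; the radius law is
#' shared between phases.
#'
#' Swelling with hydration time is a multiplicative factor on the whole
#' thickness law, `s(h) = sinf - (sinf - 1) * exp(-rate * h)`, anchored so
#' that `s(1) = swell_s1` (a 6% first-hour increase by default) and, unless
#' `swell_sinf` is supplied, so that the hour-4 zero-pressure thickness
#' equals `swell_t4_um` (1222.47 um by default).
#'
#' The default `Dmax` is chosen so that the loading-phase displacement gain
#' between 2 and `60` mmHg equals 143 um.
#'
#' @param a,b,c Thickness-law coefficients (um, um * mmHg^-c, unitless).
#' @param r0,r1 Radius-law intercept (mm) and slope (mm/mmHg).
#' @param Dmax Asymptotic apex displacement (um); default calibrated as above.
#' @param Pc Displacement pressure constant (mmHg).
#' @param lam Unloading pressure-lag factor (>= 0); 0 closes the loop.
#' @param swell_s1 Swelling factor at hour 1.
#' @param swell_sinf Swelling plateau; if `NULL`, solved from `swell_t4_um`.
#' @param swell_t4_um Target hour-4 zero-pressure thickness (um) used to
#'   solve the plateau when `swell_sinf` is `NULL`.
#' @param H2 Interior apical (cap) height at the 2 mmHg reference (mm).
#' @param B Cap base width (mm).
#'
#' @return An object of class `fwd_params` (a named list).
#' @export
#' @examples
#' p <- forward_params()
#' p$Dmax
forward_params <- function(a = 1085.5, b = 57.3, c = 0.265,
                           r0 = 8.448, r1 = 0.005,
                           Dmax = NULL, Pc = 12, lam = 0.25,
                           swell_s1 = 1.06, swell_sinf = NULL,
                           swell_t4_um = 1222.47,
                           H2 = 3.0, B = 5.25) {
  if (a <= 0) abort("`a` must be positive.")
  if (c <= 0 || c >= 1) abort("`c` must lie in (0, 1).")
  if (r0 <= 0) abort("`r0` must be positive.")
  if (Pc <= 0) abort("`Pc` must be positive.")
  if (lam < 0) abort("`lam` must be >= 0.")
  if (H2 <= 0) abort("`H2` must be positive.")
  if (B <= 0) abort("`B` must be positive.")
  if (swell_s1 < 1) abort("`swell_s1` must be >= 1.")
  if (is.null(Dmax)) {
    # default anchors D(60) - D(2) at 143 um on the loading curve
    Dmax <- 143 / (exp(-2 / Pc) - exp(-60 / Pc))
  }
  if (Dmax < 0) abort("`Dmax` must be >= 0.")
  if (is.null(swell_sinf)) {
    s4 <- swell_t4_um / a
    if (s4 < swell_s1) abort("hour-4 swelling target is below the hour-1 factor.")
    swell_sinf <- solve_swell_plateau(swell_s1, s4)
  }
  if (swell_sinf < swell_s1) abort("`swell_sinf` must be >= `swell_s1`.")
  rate <- if (swell_sinf > 1) {
    -log((swell_sinf - swell_s1) / (swell_sinf - 1))
  } else {
    Inf # no swelling at all
  }
  structure(
    list(
      a = a, b = b, c = c, r0 = r0, r1 = r1,
      Dmax = Dmax, Pc = Pc, lam = lam,
      swell_s1 = swell_s1, swell_sinf = swell_sinf, swell_rate = rate,
      H2 = H2, B = B
    ),
    class = "fwd_params"
  )
}

# Solve the plateau sinf of s(h) = sinf - (sinf - 1) exp(-rate h) such that
# s(1) = s1 and s(4) = s4. Eliminating rate gives
# ((sinf - s1)/(sinf - 1))^4 = (sinf - s4)/(sinf - 1).
solve_swell_plateau <- function(s1, s4) {
  if (abs(s4 - s1) < 1e-12) return(s1)
  f <- function(sinf) {
    ((sinf - s1) / (sinf - 1))^4 - (sinf - s4) / (sinf - 1)
  }
  lo <- s4 + 1e-9
  hi <- s4 + 10
  while (f(lo) * f(hi) > 0 && hi < 1e6) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' @export
print.fwd_params <- function(x, ...) {
  cat("<fwd_params>\n")
  cat(sprintf("  thickness: T(P) = s(h) * (%.4g - %.4g * P^%.4g) um\n", x$a, x$b, x$c))
  cat(sprintf("  radius:    R(P) = %.4g - %.4g * P mm\n", x$r0, x$r1))
  cat(sprintf("  displ.:    D(P) = %.4g * (1 - exp(-P/%.4g)) um, lag %.3g\n",
              x$Dmax, x$Pc, x$lam))
  cat(sprintf("  swelling:  s1 = %.4g, plateau = %.5g, rate = %.4g /h\n",
              x$swell_s1, x$swell_sinf, x$swell_rate))
  cat(sprintf("  cap:       H2 = %.3g mm, B = %.3g mm\n", x$H2, x$B))
  invisible(x)
}

#' Optical/rendering configuration for synthetic B-scans
#'
#' @param axial_um_per_px Axial sampling in air (um per pixel). Must not
#'   exceed `psf_fwhm_um` so the point-spread function is resolved.
#' @param lateral_um_per_px Lateral sampling (um per pixel).
#' @param n_group Group refractive index of corneal tissue (default 1.389).
#' @param psf_fwhm_um Axial point-spread FWHM in tissue (default 3.5 um).
#' @param speckle_sigma Log-scale of the multiplicative speckle noise
#'   (0 disables noise).
#' @param background_level Background intensity (0..1).
#' @param seed Integer seed from which all rendering noise flows.
#' @param lateral_fov_mm Lateral field of view (>= 6 mm so the central 3 mm
#'   analysis window fits with margin).
#' @param axial_fov_um Axial (optical-depth) extent of the image.
#' @param apex_offset_um Optical depth of the anterior apex when the apex
#'   displacement is zero; the apex moves up (toward the instrument) by the
#'   displacement D.
#'
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(axial_um_per_px = 2, lateral_um_per_px = 10,
                          n_group = 1.389, psf_fwhm_um = 3.5,
                          speckle_sigma = 0.3, background_level = 0.02,
                          seed = 42L,
                          lateral_fov_mm = 8, axial_fov_um = 3300,
                          apex_offset_um = 450) {
  if (n_group <= 1) abort("`n_group` must exceed 1.")
  if (psf_fwhm_um <= 0) abort("`psf_fwhm_um` must be positive.")
  if (axial_um_per_px <= 0 || lateral_um_per_px <= 0) {
    abort("pixel pitches must be positive.")
  }
  if (axial_um_per_px > psf_fwhm_um) {
    abort("`axial_um_per_px` must not exceed `psf_fwhm_um` (PSF must be resolved).")
  }
  if (speckle_sigma < 0) abort("`speckle_sigma` must be >= 0.")
  if (lateral_fov_mm < 6) {
    abort("`lateral_fov_mm` must be >= 6 so the central 3 mm window fits.")
  }
  structure(
    list(
      axial_um_per_px = axial_um_per_px,
      lateral_um_per_px = lateral_um_per_px,
      n_group = n_group, psf_fwhm_um = psf_fwhm_um,
      speckle_sigma = speckle_sigma, background_level = background_level,
      seed = as.integer(seed),
      lateral_fov_mm = lateral_fov_mm, axial_fov_um = axial_fov_um,
      apex_offset_um = apex_offset_um
    ),
    class = "optics_config"
  )
}

#' @export
print.optics_config <- function(x, ...) {
  cat("<optics_config>\n")
  cat(sprintf("  sampling: %.3g um/px axial (air), %.3g um/px lateral\n",
              x$axial_um_per_px, x$lateral_um_per_px))
  cat(sprintf("  field:    %.3g mm lateral x %.4g um axial\n",
              x$lateral_fov_mm, x$axial_fov_um))
  cat(sprintf("  optics:   n = %.4g, PSF FWHM = %.3g um\n", x$n_group, x$psf_fwhm_um))
  cat(sprintf("  noise:    speckle sigma = %.3g, background = %.3g, seed = %d\n",
              x$speckle_sigma, x$background_level, x$seed))
  invisible(x)
}

#' Surface-detection settings
#'
#' @param k_mad Threshold factor: a column's gradient peaks must exceed
#'   `median + k_mad * MAD` of that column's gradient magnitude.
#' @param median_width Width (columns, odd) of the running-median filter
#'   applied to each detected trace.
#' @param smooth_px Axial boxcar half-support (pixels, odd total width)
#'   applied to each column before taking the depth gradient.
#' @param outlier_k Columns whose residual from a local quadratic fit exceeds
#'   `outlier_k * MAD` are flagged and replaced by interpolation.
#' @param loess_span Span of the local quadratic (loess, degree 2) fit used
#'   for outlier screening.
#' @param min_detected_frac Minimum fraction of columns with both surfaces
#'   detected; below this a segmentation-failure error is raised.
#'
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(k_mad = 4, median_width = 11, smooth_px = 3,
                       outlier_k = 3, loess_span = 0.15,
                       min_detected_frac = 0.5) {
  if (median_width %% 2 == 0) abort("`median_width` must be odd.")
  if (smooth_px < 1 || smooth_px %% 2 == 0) abort("`smooth_px` must be odd and >= 1.")
  structure(
    list(
      k_mad = k_mad, median_width = as.integer(median_width),
      smooth_px = as.integer(smooth_px), outlier_k = outlier_k,
      loess_span = loess_span, min_detected_frac = min_detected_frac
    ),
    class = "seg_params"
  )
}

#' Mechanics configuration
#'
#' @param v Poisson's ratio (default 0.40, slightly compressible cornea).
#' @param mmhg_to_kpa_factor kPa per mmHg.
#' @param ref_phase,ref_pressure Phase and pressure (mmHg) of the strain
#'   reference state (default: loading at 2 mmHg, where the cornea first
#'   exhibits stable curvature).
#'
#' @return An object of class `mechanics_config`.
#' @export
mechanics_config <- function(v = 0.40, mmhg_to_kpa_factor = 0.1333224,
                             ref_phase = "loading", ref_pressure = 2) {
  if (v < 0 || v >= 0.5) abort("Poisson's ratio `v` must lie in [0, 0.5).")
  structure(
    list(
      v = v, mmhg_to_kpa_factor = mmhg_to_kpa_factor,
      ref_phase = ref_phase, ref_pressure = ref_pressure
    ),
    class = "mechanics_config"
  )
}
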