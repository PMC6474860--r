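check_physical <- function(traces) {
  if (identical(attr(traces, "depths"), "optical")) {
    abort("traces are in optical depths; apply correct_refraction() first.")
  }
  invisible(traces)
}

# columns within +/- window/2 of the apex column (apex = minimum anterior
# depth of the filtered trace); errors if the window is not fully covered
central_window <- function(traces, window_mm = 3) {
  # ties (e.g. a flat slab) resolve to the candidate nearest the trace centre
  cand <- which(traces$anterior_um == min(traces$anterior_um))
  apex_col <- cand[which.min(abs(traces$x_um[cand] - mean(range(traces$x_um))))]
  x0 <- traces$x_um[apex_col]
  half <- window_mm * 1000 / 2
  lo <- x0 - half
  hi <- x0 + half
  if (lo < min(traces$x_um) || hi > max(traces$x_um)) {
    abort(sprintf(
      "the central %.3g mm window around the apex is not fully covered by the traces.",
      window_mm
    ))
  }
  which(traces$x_um >= lo & traces$x_um <= hi)
}

#' Mean apex thickness over the central 3 mm
#'
#' Mean per-column axial physical distance between the posterior and
#' anterior boundaries over a window centred on the apex column (the
#' minimum of the anterior trace).
#'
#' @param traces A refraction-corrected `surface_pair`.
#' @param window_mm Averaging window (chord length, default 3 mm).
#' @return Thickness in micrometres.
#' @export
apex_thickness <- function(traces, window_mm = 3) {
  check_physical(traces)
  idx <- central_window(traces, window_mm)
  mean(traces$posterior_um[idx] - traces$anterior_um[idx])
}

# algebraic (Kasa) least-squares circle through (x, z): minimises the
# residuals of x^2 + z^2 + D x + E z + F = 0
fit_circle_kasa <- function(x, z) {
  if (length(x) < 3) abort("degenerate fit: need at least 3 points.")
  A <- cbind(x, z, 1)
  b <- -(x^2 + z^2)
  qrA <- qr(A)
  if (qrA$rank < 3) abort("degenerate fit: points are collinear.")
  dev <- unname(qr.coef(qrA, b))
  cx <- -dev[1] / 2
  cz <- -dev[2] / 2
  r2 <- cx^2 + cz^2 - dev[3]
  if (!is.finite(r2) || r2 <= 0) abort("degenerate fit: points are collinear.")
  list(cx = cx, cz = cz, r = sqrt(r2))
}

#' Anterior radius of curvature by least-squares circle fit
#'
#' Fits the algebraic least-squares circle to the anterior boundary points
#' within the central window and returns its radius. Exact for points
#' sampled on a circle; the centre is constrained only by the fit.
#'
#' @param traces A refraction-corrected `surface_pair`.
#' @param window_mm Fit chord length (default 3 mm, the thickness window).
#' @return Radius in millimetres.
#' @export
fit_radius <- function(traces, window_mm = 3) {
  check_physical(traces)
  idx <- central_window(traces, window_mm)
  fit <- fit_circle_kasa(traces$x_um[idx] / 1000, traces$anterior_um[idx] / 1000)
  fit$r
}

# robust apex depth: apex of the least-squares circle through the central
# window (centre at depth cz below the surface, so apex depth = cz - r)
apex_depth <- function(traces, window_mm = 3) {
  idx <- central_window(traces, window_mm)
  fit <- fit_circle_kasa(traces$x_um[idx], traces$anterior_um[idx])
  fit$cz - fit$r
}

#' Apex displacement relative to a reference trace
#'
#' `dD = (reference anterior apex depth) - (current anterior apex depth)`,
#' positive when the cornea bulges toward the instrument. Apex depths are
#' taken from the least-squares circle fitted over the central window,
#' which averages boundary noise across all window columns.
#'
#' @param current,reference Refraction-corrected `surface_pair`s; the
#'   reference is conventionally the 2 mmHg loading state.
#' @param window_mm Circle-fit window (default 3 mm).
#' @return Displacement in micrometres.
#' @export
apex_displacement <- function(current, reference, window_mm = 3) {
  if (is.null(reference)) abort("missing reference trace.")
  check_physical(current)
  check_physical(reference)
  apex_depth(reference, window_mm) - apex_depth(current, window_mm)
}

#' Interior cap height update
#'
#' `H = H2 + dD/1000 + dT/1000` (mm), with `dT = T2 - T`: the posterior
#' apex rises by the anterior apex rise plus the apex thinning.
#'
#' @param H2 Cap height at the 2 mmHg reference (mm, > 0).
#' @param dD_um Apex displacement relative to the reference (um).
#' @param dT_um Apex thinning relative to the reference, `T2 - T` (um).
#' @return Cap height in millimetres (> 0).
#' @export
#' @examples
#' cap_height(3.0, dD_um = 143, dT_um = 52)
cap_height <- function(H2, dD_um, dT_um) {
  if (any(H2 <= 0)) abort("`H2` must be positive.")
  H <- H2 + dD_um / 1000 + dT_um / 1000
  if (any(H <= 0)) abort("cap height must remain positive.")
  H
}

#' Parabolic cap volume
#'
#' `V = (pi/2) * H * B^2` for a parabolic cap of height `H` over a base of
#' width `B`. Linear in `H`, quadratic in `B`.
#'
#' @param H Cap height (mm, >= 0).
#' @param B Base width (mm, > 0; 5.25 mm for the clamped cornea).
#' @return Volume in cubic millimetres.
#' @export
#' @examples
#' cap_volume(3.0, 5.25)
cap_volume <- function(H, B = 5.25) {
  if (any(H < 0)) abort("`H` must be >= 0.")
  if (any(B <= 0)) abort("`B` must be positive.")
  (pi / 2) * H * B^2
}

#' Extract a geometry series from a B-scan stack
#'
#' Runs [detect_surfaces()] and [correct_refraction()] on every scan, then
#' measures apex thickness, anterior radius and apex displacement relative
#' to the 2 mmHg loading scan of the same hydration hour, and updates the
#' cap height. Displacements are reported on the generator's datum
#' (`D_um = dD + D(2 mmHg)` is not recoverable from images, so `D_um` here
#' is the displacement relative to the 2 mmHg reference, shifted to zero at
#' that reference).
#'
#' @param stack List of `bscan` objects (e.g. from [render_stack()]).
#' @param schedule Schedule tibble aligned with `stack` (same order).
#' @param params A [seg_params()].
#' @param H2 Cap height at the 2 mmHg reference (mm).
#' @param window_mm Analysis window (default 3 mm).
#' @return A `geometry_series` tibble (provenance `"measured-from-image"`)
#'   with columns `P_mmHg`, `phase`, `hour`, `T_um`, `R_mm`, `D_um`, `H_mm`.
#' @export
extract_geometry <- function(stack, schedule, params = seg_params(),
                             H2 = 3.0, window_mm = 3) {
  validate_schedule(schedule)
  if (length(stack) != nrow(schedule)) {
    abort("`stack` and `schedule` must have the same length.")
  }
  traces <- purrr::map(stack, function(b) {
    correct_refraction(detect_surfaces(b, params))
  })
  out <- schedule |>
    dplyr::select(dplyr::any_of("step"), "P_mmHg", "phase", "hour") |>
    dplyr::mutate(
      T_um = purrr::map_dbl(traces, apex_thickness, window_mm = window_mm),
      R_mm = purrr::map_dbl(traces, fit_radius, window_mm = window_mm),
      .apex = purrr::map_dbl(traces, apex_depth, window_mm = window_mm)
    )
  out <- out |>
    dplyr::group_by(.data$hour) |>
    dplyr::mutate(
      D_um = {
        ref <- which(.data$phase == "loading" & .data$P_mmHg == 2)
        if (length(ref) == 0) {
          rep(NA_real_, dplyr::n())
        } else {
          .data$.apex[ref[1]] - .data$.apex
        }
      },
      H_mm = {
        ref <- which(.data$phase == "loading" & .data$P_mmHg == 2)
        if (length(ref) == 0) {
          rep(NA_real_, dplyr::n())
        } else {
          cap_height(H2, .data$D_um - .data$D_um[ref[1]],
                     .data$T_um[ref[1]] - .data$T_um)
        }
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".apex") |>
    dplyr::mutate(provenance = "measured-from-image")
  as_geometry_series(out)
}
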