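#' Hydration swelling factor
#'
#' Multiplicative thickness factor after `hour` hours of immersion:
#' `s(h) = sinf - (sinf - 1) * exp(-rate * h)`, with `s(0) = 1`, `s(1)` equal
#' to the configured first-hour factor (1.06 by default) and a plateau
#' `sinf` anchored so the hour-4 zero-pressure thickness matches its
#' configured maximum. Non-decreasing in `hour` and bounded by `sinf`.
#'
#' @param hour Hydration time in hours (vectorised, >= 0).
#' @param params A [forward_params()] object.
#' @return Dimensionless multiplier(s) >= 1.
#' @export
#' @examples
#' swelling_factor(c(0, 1, 4), forward_params())
swelling_factor <- function(hour, params = forward_params()) {
  if (any(hour < 0)) abort("`hour` must be >= 0.")
  sinf <- params$swell_sinf
  if (!is.finite(params$swell_rate)) return(rep(1, length(hour)))
  sinf - (sinf - 1) * exp(-params$swell_rate * hour)
}

# Loading-law primitives (thickness um, radius mm, displacement um).
thickness_law <- function(P, params, hour = 0) {
  swelling_factor(hour, params) * (params$a - params$b * P^params$c)
}
radius_law <- function(P, params) params$r0 - params$r1 * P
displacement_law <- function(P, params) params$Dmax * (1 - exp(-P / params$Pc))

#' Simulate ground-truth corneal geometry over a pressure schedule
#'
#' Forward-models the geometry of a pressurised cornea at every schedule
#' step. On loading, thickness follows the shifted power law, radius the
#' linear law and apex displacement the saturating exponential (see
#' [forward_params()]). Unloading evaluates thickness and displacement at the
#' lagged pressure `P * (1 + lam)` -- the cornea stays thinner and more
#' displaced than at the same pressure on loading, opening the hysteresis
#' loop -- while the radius law is shared between phases. The interior cap
#' height is updated as `H = H2 + dD/1000 + (T2 - T)/1000` (mm), where the
#' subscript 2 marks the 2 mmHg loading state of the same hydration hour:
#' the posterior apex rises by the anterior rise plus the thinning.
#'
#' @param schedule A schedule tibble from [pressure_schedule()] (columns
#'   `P_mmHg`, `phase`, `hour`).
#' @param params A [forward_params()] object.
#' @return A `geometry_series` tibble with columns `P_mmHg`, `phase`, `hour`,
#'   `T_um`, `R_mm`, `D_um`, `H_mm`, `provenance`.
#' @export
#' @examples
#' simulate_geometry(pressure_schedule(), forward_params())
simulate_geometry <- function(schedule, params = forward_params()) {
  validate_schedule(schedule)
  if (!inherits(params, "fwd_params")) abort("`params` must be a `fwd_params` object.")
  p_eff <- schedule$P_mmHg *
    ifelse(schedule$phase == "unloading", 1 + params$lam, 1)
  out <- schedule |>
    dplyr::select(dplyr::any_of("step"), "P_mmHg", "phase", "hour") |>
    dplyr::mutate(
      T_um = thickness_law(p_eff, params, hour = .data$hour),
      R_mm = radius_law(.data$P_mmHg, params),
      D_um = displacement_law(p_eff, params)
    )
  if (any(out$T_um <= 0)) {
    abort("invalid parameters: thickness law yields non-positive thickness.")
  }
  if (any(out$R_mm[out$P_mmHg >= 2] <= 0)) {
    abort("invalid parameters: radius law yields non-positive radius.")
  }
  # cap height relative to the 2 mmHg loading state of the same hour
  out <- out |>
    dplyr::group_by(.data$hour) |>
    dplyr::mutate(H_mm = {
      ref <- which(.data$phase == "loading" & .data$P_mmHg == 2)
      if (length(ref) == 0) {
        rep(NA_real_, dplyr::n())
      } else {
        ref <- ref[1]
        params$H2 + (.data$D_um - .data$D_um[ref]) / 1000 +
          (.data$T_um[ref] - .data$T_um) / 1000
      }
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(provenance = "simulated-truth")
  as_geometry_series(out)
}

as_geometry_series <- function(x) {
  x <- as_tibble(x)
  class(x) <- c("geometry_series", class(x))
  x
}

#' Calibrate the displacement amplitude to a target displacement gain
#'
#' Sets `Dmax` so that the loading-phase displacement gain between the
#' reference and peak pressures, `D(p_hi) - D(p_lo)`, equals `target_um`
#' (closed form for the saturating-exponential law).
#'
#' @param target_um Target displacement gain in micrometres.
#' @param base Base [forward_params()].
#' @param p_lo,p_hi Reference and peak pressures (mmHg).
#' @return A `fwd_params` object with adjusted `Dmax`.
#' @export
calibrate_dmax_to_displacement <- function(target_um = 143,
                                           base = forward_params(),
                                           p_lo = 2, p_hi = 60) {
  if (target_um < 0) abort("`target_um` must be >= 0.")
  span <- exp(-p_lo / base$Pc) - exp(-p_hi / base$Pc)
  update_params(base, Dmax = target_um / span)
}

# rebuild a fwd_params with some fields replaced (re-validates invariants)
update_params <- function(params, ...) {
  repl <- list(...)
  fields <- list(
    a = params$a, b = params$b, c = params$c,
    r0 = params$r0, r1 = params$r1,
    Dmax = params$Dmax, Pc = params$Pc, lam = params$lam,
    swell_s1 = params$swell_s1, swell_sinf = params$swell_sinf,
    H2 = params$H2, B = params$B
  )
  fields[names(repl)] <- repl
  do.call(forward_params, fields)
}

# default calibration pipeline: noiseless analytic geometry -> mechanics
analytic_e15 <- function(params, P = 15, hour = 0) {
  sched <- pressure_schedule(hours = hour)
  series <- simulate_geometry(sched, params)
  curves <- build_curves(series, mechanics_config(), B = params$B)
  modulus_at(curves, P = P, phase = "loading", hour = hour)
}

#' Calibrate the displacement amplitude to a target tangent modulus
#'
#' Adjusts `Dmax` (all other parameters fixed) by bisection so that running
#' the noiseless analysis pipeline on the fresh-cornea schedule yields a
#' loading-phase tangent modulus at 15 mmHg within `tol_rel` of
#' `target_E15`. Larger `Dmax` means more volumetric strain per unit stress
#' and hence a lower modulus, so the map is monotone decreasing. The
#' bisection bracket is widened geometrically until the target is straddled.
#'
#' @param target_E15 Target loading-phase tangent modulus at 15 mmHg (kPa).
#' @param base Base [forward_params()].
#' @param pipeline A callable `function(params) -> E15 (kPa)`; the default
#'   runs [simulate_geometry()] + [build_curves()] on the fresh-cornea
#'   schedule with no imaging noise.
#' @param tol_rel Relative tolerance on the achieved modulus (default 1e-3,
#'   i.e. 0.1%).
#' @param max_expand Maximum number of geometric bracket expansions.
#' @return A `fwd_params` object whose `Dmax` meets the target.
#' @export
calibrate_to_modulus <- function(target_E15, base = forward_params(),
                                 pipeline = analytic_e15,
                                 tol_rel = 1e-3, max_expand = 60) {
  if (target_E15 <= 0) abort("`target_E15` must be positive.")
  f <- function(dmax) pipeline(update_params(base, Dmax = dmax)) - target_E15
  lo <- base$Dmax / 4
  hi <- base$Dmax * 4
  flo <- f(lo)
  fhi <- f(hi)
  n <- 0
  # E decreases with Dmax: want f(lo) > 0 > f(hi)
  while (flo < 0 && n < max_expand) {
    lo <- lo / 2
    flo <- f(lo)
    n <- n + 1
  }
  while (fhi > 0 && n < max_expand) {
    hi <- hi * 2
    fhi <- f(hi)
    n <- n + 1
  }
  if (flo * fhi > 0) {
    abort(sprintf(
      "calibration failure: target %.4g kPa not straddled; achieved range [%.4g, %.4g] kPa.",
      target_E15, target_E15 + min(flo, fhi), target_E15 + max(flo, fhi)
    ))
  }
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    fm <- f(mid)
    if (abs(fm) / target_E15 < tol_rel / 2) break
    if (fm > 0) lo <- mid else hi <- mid
  }
  update_params(base, Dmax = mid)
}

#' Calibrate the unloading pressure lag to a target hysteresis
#'
#' Adjusts `lam` by bisection so the noiseless fresh-cornea pipeline yields
#' a loading/unloading loop area of `target_mmHg` (in mmHg units). The loop
#' area is monotone increasing in `lam` but bounded above by the area under
#' the loading curve, so large targets can be unreachable; in that case a
#' calibration-failure error reports the achievable ceiling.
#'
#' @param target_mmHg Target loop area in mmHg equivalents.
#' @param base Base [forward_params()].
#' @param tol_rel Relative tolerance (default 1e-3).
#' @return A `fwd_params` object with adjusted `lam`.
#' @export
calibrate_lam_to_hysteresis <- function(target_mmHg, base = forward_params(),
                                        tol_rel = 1e-3) {
  if (target_mmHg <= 0) abort("`target_mmHg` must be positive.")
  loop_mmhg <- function(lam) {
    series <- simulate_geometry(pressure_schedule(), update_params(base, lam = lam))
    curves <- build_curves(series, mechanics_config(), B = base$B)
    hysteresis(curves)$hysteresis_mmHg
  }
  # the loop area rises with lam, peaks, then falls as the strain-range
  # intersection shrinks; calibrate on the rising branch only
  grid <- seq(0, 8, by = 0.25)
  areas <- purrr::map_dbl(grid, loop_mmhg)
  peak <- which.max(areas)
  if (target_mmHg > areas[peak]) {
    abort(sprintf(
      "calibration failure: target %.4g mmHg exceeds the achievable loop area (<= %.4g mmHg under these parameters).",
      target_mmHg, areas[peak]
    ))
  }
  hi_i <- which(areas[seq_len(peak)] >= target_mmHg)[1]
  if (hi_i == 1) return(update_params(base, lam = 0))
  lo <- grid[hi_i - 1]
  hi <- grid[hi_i]
  mid <- hi
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    fm <- loop_mmhg(mid)
    if (abs(fm - target_mmHg) / target_mmHg < tol_rel / 2) break
    if (fm < target_mmHg) lo <- mid else hi <- mid
  }
  update_params(base, lam = mid)
}

#' Generate replicate "eyes" by jittering forward-model parameters
#'
#' Emulates between-animal variability by multiplying the thickness
#' intercept `a`, the displacement amplitude `Dmax` and the first-hour
#' swelling gain (`swell_s1 - 1`) of a base parameter set by independent
#' log-normal-free Gaussian factors `1 + rel_sd * Z`.
#'
#' @param n_eyes Number of replicate corneas.
#' @param base Base [forward_params()].
#' @param rel_sd Relative jitter (default 0.03).
#' @param seed Integer seed.
#' @return A list of `fwd_params`, one per eye.
#' @export
simulate_eyes <- function(n_eyes = 8, base = forward_params(),
                          rel_sd = 0.03, seed = 42L) {
  withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(n_eyes), function(i) {
      fac <- 1 + rel_sd * rnorm(3)
      fac <- pmax(fac, 0.5)
      update_params(
        base,
        a = base$a * fac[1],
        Dmax = base$Dmax * fac[2],
        swell_s1 = 1 + (base$swell_s1 - 1) * fac[3],
        # keep the plateau consistent with the jittered first-hour gain
        swell_sinf = max(base$swell_sinf, 1 + (base$swell_s1 - 1) * fac[3])
      )
    })
  })
}
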