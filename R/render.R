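#' Render a synthetic LF-OCT B-scan of one geometry state
#'
#' Builds a calibrated 2-D intensity image (rows = optical depth, columns =
#' lateral position) of a cornea in a given geometry state. The anterior
#' surface is a circular arc of radius `R_mm` whose apex sits at optical
#' depth `apex_offset_um - D_um`; below it the image is laid out in optical
#' path length, so the anterior-to-posterior gap equals `n_group * T_um` and
#' an epithelium interface of distinct reflectivity sits at
#' `n_group * 100` um below the anterior surface. Surface edges are rendered
#' with sub-pixel (area-weighted) coverage, blurred axially with a Gaussian
#' point-spread function of FWHM `psf_fwhm_um`, and finally multiplied by
#' log-normal speckle of scale `speckle_sigma`. Identical
#' `(state, optics, seed)` give a bit-identical image.
#'
#' @param state A single geometry state: one row of a `geometry_series` (or
#'   any list with `T_um`, `R_mm`, `D_um`).
#' @param optics An [optics_config()].
#' @param seed Seed for the speckle field; defaults to `optics$seed`.
#' @return A `bscan` object: list with `pixels` (matrix, arbitrary intensity
#'   units in \[0, ~1.5\]), the calibration scalars and the state metadata.
#' @export
#' @examples
#' st <- simulate_geometry(pressure_schedule(), forward_params())[3, ]
#' b <- render_bscan(st, optics_config(speckle_sigma = 0))
#' dim(b$pixels)
render_bscan <- function(state, optics = optics_config(), seed = optics$seed) {
  if (is.data.frame(state)) {
    if (nrow(state) != 1) abort("`state` must be a single geometry state (one row).")
    state <- as.list(state)
  }
  for (f in c("T_um", "R_mm", "D_um")) {
    if (is.null(state[[f]]) || !is.finite(state[[f]])) {
      abort(paste0("`state` is missing field ", f, "."))
    }
  }
  ax <- optics$axial_um_per_px
  lat <- optics$lateral_um_per_px
  n_gr <- optics$n_group
  nc <- round(optics$lateral_fov_mm * 1000 / lat)
  nr <- round(optics$axial_fov_um / ax)

  R_um <- state$R_mm * 1000
  x <- (seq_len(nc) - (nc + 1) / 2) * lat # lateral position, image centre = apex
  if (max(abs(x)) >= R_um) {
    abort("field-of-view error: lateral field exceeds the surface radius.")
  }
  # anterior arc (air, so optical depth = physical depth)
  za <- optics$apex_offset_um - state$D_um + (R_um - sqrt(R_um^2 - x^2))
  gap_opt <- n_gr * state$T_um # as-imaged anterior-posterior gap
  zp <- za + gap_opt
  epi <- za + n_gr * 100 # epithelium interface, 100 um physical
  if (min(za) < 5 * ax || max(zp) > (nr - 5) * ax) {
    abort("field-of-view error: surfaces fall outside the axial field.")
  }

  # area-weighted band coverage: pixel i spans optical depth [(i-1)*ax, i*ax]
  zlo <- matrix((seq_len(nr) - 1) * ax, nr, nc)
  zhi <- zlo + ax
  cov_band <- function(lo, hi) {
    lo_m <- matrix(lo, nr, nc, byrow = TRUE)
    hi_m <- matrix(hi, nr, nc, byrow = TRUE)
    # matrix first so pmax/pmin keep the dim attribute
    pmax(pmin(zhi, hi_m) - pmax(zlo, lo_m), 0) / ax
  }
  bg <- optics$background_level
  line_w <- 4 # um, bright interface lines
  img <- bg +
    (0.55 - bg) * cov_band(za, epi) + # epithelium band
    (0.40 - bg) * cov_band(epi, zp) + # stroma band
    (1.00 - 0.55) * cov_band(za, za + line_w) + # anterior surface line
    (0.85 - 0.40) * cov_band(zp - line_w, zp) # posterior surface line

  img <- blur_axial(img, optics$psf_fwhm_um / ax)

  if (optics$speckle_sigma > 0) {
    s <- optics$speckle_sigma
    img <- withr::with_seed(as.integer(seed), {
      img * exp(s * matrix(rnorm(nr * nc), nr, nc) - s^2 / 2)
    })
  }

  structure(
    list(
      pixels = img,
      axial_um_per_px = ax, lateral_um_per_px = lat, n_group = n_gr,
      psf_fwhm_um = optics$psf_fwhm_um, speckle_sigma = optics$speckle_sigma,
      seed = as.integer(seed),
      state = state[intersect(
        c("step", "P_mmHg", "phase", "hour", "T_um", "R_mm", "D_um", "H_mm"),
        names(state)
      )]
    ),
    class = "bscan"
  )
}

# Gaussian axial blur, column-wise, FWHM given in pixels. Edge rows are
# padded by replication so surfaces near borders are not darkened.
blur_axial <- function(img, fwhm_px) {
  sigma <- fwhm_px / (2 * sqrt(2 * log(2)))
  if (sigma < 1e-6) return(img)
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  nr <- nrow(img)
  padded <- rbind(
    img[rep(1L, half), , drop = FALSE],
    img,
    img[rep(nr, half), , drop = FALSE]
  )
  out <- stats::filter(padded, k, method = "convolution", sides = 2)
  matrix(out[(half + 1):(half + nr), ], nr, ncol(img))
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf(
    "<bscan> %d x %d px (%.3g um/px axial, %.3g um/px lateral), n = %.4g\n",
    nrow(x$pixels), ncol(x$pixels), x$axial_um_per_px, x$lateral_um_per_px,
    x$n_group
  ))
  if (!is.null(x$state$P_mmHg)) {
    cat(sprintf(
      "  state: P = %g mmHg, %s, hour %g; T = %.4g um, R = %.4g mm, D = %.4g um\n",
      x$state$P_mmHg, x$state$phase %||% "?", x$state$hour %||% 0,
      x$state$T_um, x$state$R_mm, x$state$D_um
    ))
  }
  invisible(x)
}

#' Render a B-scan stack for a whole geometry series
#'
#' One B-scan per row of `series`. Per-scan speckle seeds are derived
#' deterministically from `optics$seed` plus the row index, so the stack is
#' reproducible and each scan's noise is independent.
#'
#' @param series A `geometry_series` tibble (simulated truth).
#' @param optics An [optics_config()].
#' @return A list of `bscan` objects of length `nrow(series)`.
#' @export
render_stack <- function(series, optics = optics_config()) {
  purrr::map(seq_len(nrow(series)), function(i) {
    render_bscan(series[i, ], optics, seed = optics$seed + i)
  })
}
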