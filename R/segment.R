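#' Detect anterior and posterior corneal boundaries in a B-scan
#'
#' Fully automated column-wise boundary detection. For every image column
#' the axial intensity profile is lightly smoothed, its depth gradient
#' taken, and local maxima of the gradient magnitude above an adaptive
#' threshold (`median + k_mad * MAD` of the column's gradient magnitude)
#' located. The anterior boundary is the first such maximum, the posterior
#' the last one below it; peak positions are refined to sub-pixel precision
#' by a three-point parabolic fit. Both traces are then median-filtered
#' across columns and screened against a local quadratic (loess) fit:
#' columns whose residual exceeds `outlier_k * MAD` are flagged
#' `"interpolated"` and replaced by linear interpolation from their
#' neighbours. Depths are returned as *optical* path lengths; apply
#' [correct_refraction()] before geometric analysis.
#'
#' @param bscan A `bscan` object (or a list with `pixels` and calibration
#'   scalars `axial_um_per_px`, `lateral_um_per_px`, `n_group`).
#' @param params A [seg_params()] object.
#' @return A `surface_pair` tibble with columns `column`, `x_um` (lateral
#'   position, image frame), `anterior_um`, `posterior_um` (optical depths),
#'   `quality` (`"detected"` or `"interpolated"`). Calibration scalars and
#'   `depths = "optical"` are attached as attributes.
#' @export
detect_surfaces <- function(bscan, params = seg_params()) {
  img <- bscan$pixels
  if (is.null(img) || !is.matrix(img)) abort("`bscan` must carry a pixel matrix.")
  if (nrow(img) < 100 || ncol(img) < 100) {
    abort("image must be at least 100 x 100 pixels.")
  }
  ax <- bscan$axial_um_per_px
  lat <- bscan$lateral_um_per_px
  nr <- nrow(img)
  nc <- ncol(img)

  # axial boxcar pre-smoothing, then central-difference depth gradient
  if (params$smooth_px > 1) {
    k <- rep(1 / params$smooth_px, params$smooth_px)
    half <- (params$smooth_px - 1L) %/% 2L
    padded <- rbind(
      img[rep(1L, half), , drop = FALSE], img,
      img[rep(nr, half), , drop = FALSE]
    )
    sm <- stats::filter(padded, k, method = "convolution", sides = 2)
    img <- matrix(sm[(half + 1):(half + nr), ], nr, nc)
  }
  g <- (img[c(2:nr, nr), ] - img[c(1, 1:(nr - 1)), ]) / 2
  ag <- abs(g)

  ant <- rep(NA_real_, nc)
  post <- rep(NA_real_, nc)
  for (j in seq_len(nc)) {
    col <- ag[, j]
    thr <- median(col) + params$k_mad * mad(col)
    # strict local maxima above threshold (interior samples only)
    core <- col[2:(nr - 1)]
    is_pk <- core > col[1:(nr - 2)] & core >= col[3:nr] & core > thr
    pk <- which(is_pk) + 1L
    if (length(pk) < 2) next
    a_idx <- pk[1]
    p_idx <- pk[length(pk)]
    if (p_idx <= a_idx) next
    ant[j] <- refine_peak(col, a_idx)
    post[j] <- refine_peak(col, p_idx)
  }

  det <- is.finite(ant) & is.finite(post)
  if (mean(det) < params$min_detected_frac) {
    abort("segmentation failure: fewer than the required fraction of columns detected.")
  }

  quality <- ifelse(det, "detected", "interpolated")
  ant <- fill_interp(ant)
  post <- fill_interp(post)

  w <- min(params$median_width, if (nc %% 2 == 1) nc else nc - 1)
  ant <- as.numeric(stats::runmed(ant, w, endrule = "median"))
  post <- as.numeric(stats::runmed(post, w, endrule = "median"))

  ant_scr <- screen_outliers(ant, params)
  post_scr <- screen_outliers(post, params)
  ant <- ant_scr$z
  post <- post_scr$z
  quality[ant_scr$flagged | post_scr$flagged] <- "interpolated"

  if (any(post <= ant)) {
    abort("segmentation inconsistency: posterior boundary above anterior after filtering.")
  }

  out <- tibble(
    column = seq_len(nc),
    x_um = (seq_len(nc) - 0.5) * lat,
    anterior_um = ant * ax,
    posterior_um = post * ax,
    quality = quality
  )
  attr(out, "axial_um_per_px") <- ax
  attr(out, "lateral_um_per_px") <- lat
  attr(out, "n_group") <- bscan$n_group
  attr(out, "depths") <- "optical"
  class(out) <- c("surface_pair", class(out))
  out
}

# sub-pixel peak position by a parabola through (idx-1, idx, idx+1);
# returns a fractional row index on the pixel-centre scale minus 0.5,
# i.e. directly multiplicable by the axial pitch.
refine_peak <- function(col, idx) {
  n <- length(col)
  if (idx <= 1 || idx >= n) return(idx - 0.5)
  y0 <- col[idx - 1]
  y1 <- col[idx]
  y2 <- col[idx + 1]
  den <- y0 - 2 * y1 + y2
  delta <- if (abs(den) < 1e-12) 0 else 0.5 * (y0 - y2) / den
  delta <- max(-0.5, min(0.5, delta))
  idx + delta - 0.5
}

fill_interp <- function(z) {
  ok <- is.finite(z)
  if (all(ok)) return(z)
  idx <- seq_along(z)
  approx(idx[ok], z[ok], xout = idx, rule = 2)$y
}

# flag columns deviating from a local quadratic (loess degree-2) trend by
# more than outlier_k * MAD and replace them by interpolation
screen_outliers <- function(z, params) {
  idx <- seq_along(z)
  fit <- suppressWarnings(
    loess(z ~ idx, span = params$loess_span, degree = 2,
          family = "gaussian", surface = "direct")
  )
  res <- z - predict(fit, idx)
  s <- mad(res)
  flagged <- if (s > 0) abs(res) > params$outlier_k * s else rep(FALSE, length(z))
  if (any(flagged) && !all(flagged)) {
    z[flagged] <- approx(idx[!flagged], z[!flagged], xout = idx[flagged], rule = 2)$y
  }
  list(z = z, flagged = flagged)
}

#' Convert optical depths to physical depths via the group refractive index
#'
#' The anterior trace is measured through air and is left unchanged; the
#' anterior-to-posterior *optical* gap in each column is divided by the
#' group refractive index, so physical thickness = optical thickness /
#' `n_group`. Lateral ray bending at the anterior surface is ignored
#' (near-normal incidence at the apex); only the axial path length is
#' corrected.
#'
#' @param traces A `surface_pair` from [detect_surfaces()] (optical depths).
#' @param n_group Group refractive index (>= 1); defaults to the value
#'   recorded on `traces`.
#' @return The `surface_pair` with `posterior_um` in physical micrometres
#'   and attribute `depths = "physical"`.
#' @export
#' @examples
#' # a 1389 um optical gap across n = 1.389 tissue is 1000 um of cornea
correct_refraction <- function(traces, n_group = attr(traces, "n_group")) {
  if (is.null(n_group)) abort("`n_group` is required.")
  if (n_group < 1) abort("`n_group` must be >= 1.")
  if (identical(attr(traces, "depths"), "physical")) {
    abort("`traces` are already refraction-corrected.")
  }
  traces$posterior_um <- traces$anterior_um +
    (traces$posterior_um - traces$anterior_um) / n_group
  attr(traces, "depths") <- "physical"
  attr(traces, "n_group") <- n_group
  traces
}
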