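geometry_cols <- c("P_mmHg", "phase", "hour", "T_um", "R_mm", "D_um", "H_mm")

#' Write / read a geometry series as CSV
#'
#' Column names carry the units (`P_mmHg`, `T_um`, `R_mm`, `D_um`, `H_mm`).
#' Numeric fields round-trip at full double precision; unknown extra
#' columns are preserved on read.
#'
#' @param series A `geometry_series` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); a `geometry_series` tibble (reader).
#' @export
write_geometry_csv <- function(series, path) {
  miss <- setdiff(geometry_cols, names(series))
  if (length(miss) > 0) {
    abort(paste0("series is missing column(s): ", paste(miss, collapse = ", ")))
  }
  readr::write_csv(as_tibble(series), path)
  invisible(path)
}

#' @rdname write_geometry_csv
#' @export
read_geometry_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(geometry_cols, names(x))
  if (length(miss) > 0) {
    abort(paste0("schema error: missing column(s): ", paste(miss, collapse = ", ")))
  }
  as_geometry_series(x)
}

#' Write / read segmented surface traces as CSV
#'
#' Columns: `column_um` (lateral position), `anterior_um`, `posterior_um`,
#' `quality`. The depth convention (optical vs physical) and calibration
#' are recorded in the attribute columns of the header comment-free CSV via
#' extra columns on write and restored as attributes on read.
#'
#' @param traces A `surface_pair` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); a `surface_pair` tibble (reader).
#' @export
write_surfaces_csv <- function(traces, path) {
  out <- tibble(
    column_um = traces$x_um,
    anterior_um = traces$anterior_um,
    posterior_um = traces$posterior_um,
    quality = traces$quality,
    depths = attr(traces, "depths") %||% "optical",
    axial_um_per_px = attr(traces, "axial_um_per_px") %||% NA_real_,
    lateral_um_per_px = attr(traces, "lateral_um_per_px") %||% NA_real_,
    n_group = attr(traces, "n_group") %||% NA_real_
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_surfaces_csv
#' @export
read_surfaces_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("column_um", "anterior_um", "posterior_um", "quality")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    abort(paste0("schema error: missing column(s): ", paste(miss, collapse = ", ")))
  }
  out <- tibble(
    column = seq_len(nrow(x)),
    x_um = x$column_um,
    anterior_um = x$anterior_um,
    posterior_um = x$posterior_um,
    quality = x$quality
  )
  attr(out, "depths") <- if ("depths" %in% names(x)) x$depths[1] else "optical"
  for (a in c("axial_um_per_px", "lateral_um_per_px", "n_group")) {
    if (a %in% names(x)) attr(out, a) <- x[[a]][1]
  }
  class(out) <- c("surface_pair", class(out))
  out
}

#' Write a B-scan stack as multi-page TIFF plus a JSON sidecar
#'
#' Images are written as 16-bit grayscale pages (intensities clipped to
#' \[0, 1\]); the sidecar records the calibration (um per pixel, group
#' index), the per-scan seeds and the schedule metadata, so the stack can
#' be reloaded without the generating session.
#'
#' @param stack List of `bscan` objects.
#' @param tiff_path Output TIFF path; the sidecar is written next to it
#'   with extension `.json`.
#' @return `tiff_path`, invisibly.
#' @export
write_bscan_stack <- function(stack, tiff_path) {
  pages <- purrr::map(stack, function(b) pmin(pmax(b$pixels, 0), 1))
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16, compression = "none")
  b1 <- stack[[1]]
  sidecar <- list(
    axial_um_per_px = b1$axial_um_per_px,
    lateral_um_per_px = b1$lateral_um_per_px,
    n_group = b1$n_group,
    psf_fwhm_um = b1$psf_fwhm_um,
    speckle_sigma = b1$speckle_sigma,
    seeds = purrr::map_int(stack, "seed"),
    schedule = purrr::map_dfr(stack, function(b) {
      as_tibble(b$state[intersect(c("P_mmHg", "phase", "hour"), names(b$state))])
    })
  )
  jsonlite::write_json(sidecar, sidecar_path(tiff_path),
                       auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

sidecar_path <- function(tiff_path) {
  paste0(tools::file_path_sans_ext(tiff_path), ".json")
}

#' Read a B-scan stack written by [write_bscan_stack()]
#'
#' @param tiff_path Path to the multi-page TIFF (sidecar JSON expected next
#'   to it).
#' @return A list of `bscan` objects.
#' @export
read_bscan_stack <- function(tiff_path) {
  side <- sidecar_path(tiff_path)
  if (!file.exists(side)) abort(paste0("sidecar JSON not found: ", side))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  purrr::imap(pages, function(px, i) {
    st <- if (!is.null(meta$schedule) && length(meta$schedule) > 0) {
      as.list(as.data.frame(meta$schedule)[i, , drop = FALSE])
    } else {
      list()
    }
    structure(
      list(
        pixels = px,
        axial_um_per_px = meta$axial_um_per_px,
        lateral_um_per_px = meta$lateral_um_per_px,
        n_group = meta$n_group,
        psf_fwhm_um = meta$psf_fwhm_um,
        speckle_sigma = meta$speckle_sigma,
        seed = as.integer(meta$seeds[i]),
        state = st
      ),
      class = "bscan"
    )
  })
}
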