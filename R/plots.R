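#' Plot a geometry series
#'
#' Thickness, anterior radius and apex displacement against pressure,
#' split by loading/unloading phase (and hydration hour when several are
#' present).
#'
#' @param object A `geometry_series` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.geometry_series <- function(object, ...) {
  long <- object |>
    as_tibble() |>
    dplyr::select("P_mmHg", "phase", "hour", "T_um", "R_mm", "D_um") |>
    tidyr::pivot_longer(c("T_um", "R_mm", "D_um"),
                        names_to = "measure", values_to = "value") |>
    dplyr::mutate(measure = factor(
      .data$measure, levels = c("T_um", "R_mm", "D_um"),
      labels = c("thickness (µm)", "radius (mm)", "displacement (µm)")
    ))
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$P_mmHg, y = .data$value,
    colour = .data$phase, group = interaction(.data$phase, .data$hour)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "IOP (mmHg)", y = NULL, colour = "phase") +
    ggplot2::theme_minimal()
  if (length(unique(long$hour)) > 1) {
    p <- p + ggplot2::aes(linetype = factor(.data$hour)) +
      ggplot2::labs(linetype = "hour")
  }
  p
}

#' Plot stress-strain loops
#'
#' Stress against volumetric strain per phase, one panel per hydration
#' hour; the enclosed area is the corneal hysteresis.
#'
#' @param object An `ss_curves` tibble from [build_curves()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ss_curves <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(
    x = .data$epsilon, y = .data$sigma_kPa, colour = .data$phase
  )) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~hour, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "volumetric strain", y = "stress (kPa)", colour = "phase"
    ) +
    ggplot2::theme_minimal()
}

#' Display a B-scan
#'
#' @param x A `bscan` object.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.bscan <- function(x, ...) {
  img <- x$pixels
  nr <- nrow(img)
  nc <- ncol(img)
  graphics::image(
    x = (seq_len(nc) - 0.5) * x$lateral_um_per_px / 1000,
    y = (seq_len(nr) - 0.5) * x$axial_um_per_px,
    z = t(img[nr:1, ]),
    col = grDevices::gray.colors(256, start = 0, end = 1),
    xlab = "lateral (mm)", ylab = "optical depth (µm, inverted)",
    useRaster = TRUE, ...
  )
  invisible(x)
}
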