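#' Assemble a pipeline run configuration
#'
#' Collects every knob of the end-to-end pipeline in one validated list.
#' Component overrides are given as named lists and merged into the
#' defaults of [pressure_schedule()], [forward_params()], [optics_config()],
#' [mechanics_config()] and [seg_params()].
#'
#' @param schedule Named list of [pressure_schedule()] arguments.
#' @param params Named list of [forward_params()] arguments.
#' @param optics Named list of [optics_config()] arguments.
#' @param mechanics Named list of [mechanics_config()] arguments.
#' @param segmentation Named list of [seg_params()] arguments.
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; recorded in every output's metadata and used to
#'   derive the per-scan speckle seeds.
#' @param verbose Log one line per stage.
#' @return A `run_config` object.
#' @export
run_config <- function(schedule = list(), params = list(), optics = list(),
                       mechanics = list(), segmentation = list(),
                       out_dir = tempfile("octrun"), seed = 42L,
                       verbose = TRUE) {
  cfg <- structure(
    list(
      schedule = do.call(pressure_schedule, schedule),
      params = do.call(forward_params, params),
      optics = do.call(optics_config, c(optics, list(seed = seed))),
      mechanics = do.call(mechanics_config, mechanics),
      segmentation = do.call(seg_params, segmentation),
      out_dir = out_dir, seed = as.integer(seed), verbose = verbose,
      overrides = list(
        schedule = schedule, params = params, optics = optics,
        mechanics = mechanics, segmentation = segmentation
      )
    ),
    class = "run_config"
  )
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file may contain any subset of the [run_config()] sections
#' (`schedule`, `params`, `optics`, `mechanics`, `segmentation`) plus
#' top-level `out_dir`, `seed` and `verbose`.
#'
#' @param path YAML file path.
#' @param out_dir Optional override of the configured output directory.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  known <- c("schedule", "params", "optics", "mechanics", "segmentation",
             "out_dir", "seed", "verbose")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config section(s): ", paste(unknown, collapse = ", ")))
  }
  run_config(
    schedule = y$schedule %||% list(),
    params = y$params %||% list(),
    optics = y$optics %||% list(),
    mechanics = y$mechanics %||% list(),
    segmentation = y$segmentation %||% list(),
    out_dir = out_dir %||% y$out_dir %||% tempfile("octrun"),
    seed = y$seed %||% 42L,
    verbose = y$verbose %||% TRUE
  )
}

#' Run the end-to-end inflation analysis pipeline
#'
#' Executes simulate -> render -> segment -> geometry -> mechanics -> fits
#' -> report. Every stage's outputs are persisted under `config$out_dir`
#' and listed, with MD5 checksums, in `manifest.json`; re-running the same
#' configuration reproduces byte-identical outputs. A failing stage aborts
#' with the stage name; outputs of completed stages remain on disk.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the truth and measured series, the
#'   traces, curves, fits, summary and manifest.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config.")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  log_stage <- function(name, t0, info = "") {
    if (config$verbose) {
      message(sprintf("[%s] %.2fs %s", name, as.numeric(Sys.time()) - t0, info))
    }
  }
  with_stage <- function(name, expr) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    attr(res, ".t0") <- t0
    res
  }

  # 1. simulate ground truth
  truth <- with_stage("simulate", simulate_geometry(config$schedule, config$params))
  f <- file.path(config$out_dir, "truth_geometry.csv")
  write_geometry_csv(truth, f)
  files <- c(files, f)
  log_stage("simulate", attr(truth, ".t0"), sprintf("%d states", nrow(truth)))

  # 2. render B-scans
  stack <- with_stage("render", render_stack(truth, config$optics))
  f <- file.path(config$out_dir, "bscans.tiff")
  write_bscan_stack(stack, f)
  files <- c(files, f, sidecar_path(f))
  log_stage("render", attr(stack, ".t0"), sprintf("%d scans", length(stack)))

  # 3. segment + refraction-correct
  traces <- with_stage("segment", purrr::map(stack, function(b) {
    correct_refraction(detect_surfaces(b, config$segmentation))
  }))
  tr_dir <- file.path(config$out_dir, "traces")
  dir.create(tr_dir, showWarnings = FALSE)
  for (i in seq_along(traces)) {
    fi <- file.path(tr_dir, sprintf("scan_%03d.csv", i))
    write_surfaces_csv(traces[[i]], fi)
    files <- c(files, fi)
  }
  log_stage("segment", attr(traces, ".t0"), sprintf("%d traces", length(traces)))

  # 4. geometry extraction
  measured <- with_stage("geometry", {
    out <- config$schedule |>
      dplyr::select(dplyr::any_of("step"), "P_mmHg", "phase", "hour") |>
      dplyr::mutate(
        T_um = purrr::map_dbl(traces, apex_thickness),
        R_mm = purrr::map_dbl(traces, fit_radius),
        .apex = purrr::map_dbl(traces, apex_depth)
      ) |>
      dplyr::group_by(.data$hour) |>
      dplyr::mutate(
        D_um = {
          ref <- which(.data$phase == "loading" & .data$P_mmHg == 2)[1]
          .data$.apex[ref] - .data$.apex
        },
        H_mm = cap_height(
          config$params$H2,
          .data$D_um - .data$D_um[which(.data$phase == "loading" & .data$P_mmHg == 2)[1]],
          .data$T_um[which(.data$phase == "loading" & .data$P_mmHg == 2)[1]] - .data$T_um
        )
      ) |>
      dplyr::ungroup() |>
      dplyr::select(-".apex") |>
      dplyr::mutate(provenance = "measured-from-image") |>
      as_geometry_series()
    out
  })
  f <- file.path(config$out_dir, "measured_geometry.csv")
  write_geometry_csv(measured, f)
  files <- c(files, f)
  t15 <- measured$T_um[measured$P_mmHg == 15 & measured$phase == "loading"]
  log_stage("geometry", attr(measured, ".t0"),
            if (length(t15) > 0) sprintf("T(15, loading) = %.1f um", t15[1]) else "")

  # 5. mechanics
  curves <- with_stage(
    "mechanics",
    build_curves(measured, config$mechanics, B = config$params$B)
  )
  f <- file.path(config$out_dir, "stress_strain.csv")
  readr::write_csv(as_tibble(curves), f)
  files <- c(files, f)
  summary_tbl <- mechanics_summary(curves)
  f <- file.path(config$out_dir, "mechanics_summary.json")
  jsonlite::write_json(summary_tbl, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  log_stage("mechanics", attr(curves, ".t0"),
            sprintf("E(15) = %.1f kPa, hysteresis = %.3f kPa",
                    summary_tbl$E_loading_kPa[1], summary_tbl$hysteresis_kPa[1]))

  # 6. empirical fits (loading phase of the first hour)
  fits <- with_stage("fits", {
    h0 <- measured[measured$hour == min(measured$hour) &
                     measured$phase == "loading", ]
    list(
      thickness = fit_thickness_power(h0),
      radius = fit_radius_linear(h0[h0$P_mmHg >= 2, ]),
      displacement = fit_displacement_exponential(h0[h0$P_mmHg >= 2, ])
    )
  })
  f <- file.path(config$out_dir, "fits.json")
  jsonlite::write_json(
    purrr::map(fits, function(x) c(x$params, list(rss = x$rss))),
    f, auto_unbox = TRUE, digits = NA
  )
  files <- c(files, f)
  log_stage("fits", attr(fits, ".t0"),
            sprintf("a = %.1f um, R0 = %.3f mm",
                    fits$thickness$params$a, fits$radius$params$intercept))

  # 7. report / manifest
  manifest <- with_stage("report", list(
    seed = config$seed,
    parameters = list(
      forward = unclass(config$params),
      optics = unclass(config$optics),
      mechanics = unclass(config$mechanics),
      segmentation = unclass(config$segmentation)
    ),
    stages = c("simulate", "render", "segment", "geometry", "mechanics",
               "fits", "report"),
    files = tibble(
      path = basename_rel(files, config$out_dir),
      md5 = unname(tools::md5sum(files))
    )
  ))
  f <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA)
  log_stage("report", attr(manifest, ".t0"), sprintf("%d files", length(files)))

  invisible(list(
    truth = truth, stack = stack, traces = traces, measured = measured,
    curves = curves, summary = summary_tbl, fits = fits, manifest = manifest,
    out_dir = config$out_dir
  ))
}

basename_rel <- function(paths, root) {
  # every path was built as file.path(root, ...): strip the prefix literally
  ifelse(startsWith(paths, paste0(root, "/")),
         substring(paths, nchar(root) + 2), paths)
}
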