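#' Percent change between two values
#'
#' `100 * (x1 - x0) / x0`.
#'
#' @param x0 Baseline value(s), non-zero.
#' @param x1 New value(s), same units.
#' @return Percent change.
#' @export
#' @examples
#' percent_change(1.4, 2.1) # 50
percent_change <- function(x0, x1) {
  if (any(x0 == 0)) abort("`x0` must be non-zero.")
  100 * (x1 - x0) / x0
}

#' Exact Wilcoxon signed-rank test for paired differences
#'
#' Two-sided exact p-value of the signed-rank statistic for small samples
#' (n <= 20 after dropping zero differences). Ties in the absolute
#' differences receive midranks. The null distribution is built by exact
#' enumeration over all `2^n` sign assignments of the ranks (evaluated by
#' convolution, which sums the same `2^n` terms), with no normal
#' approximation: `p = P(|W - E[W]| >= |w_obs - E[W]|)`.
#'
#' @param diffs Numeric vector of paired differences.
#' @return Two-sided p-value in (0, 1].
#' @export
#' @examples
#' wilcoxon_signed_rank_exact(rep(1, 8)) # 2/256
wilcoxon_signed_rank_exact <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) abort("undefined test: all differences are zero.")
  if (n > 20) abort("exact enumeration supports at most n = 20 non-zero differences.")
  r2 <- 2 * rank(abs(d)) # doubled midranks are integers
  r2 <- as.integer(round(r2))
  w_obs <- sum(r2[d > 0])
  tot <- sum(r2)
  # counts[s + 1] = number of sign assignments with doubled statistic s
  counts <- numeric(tot + 1)
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(tot + 1 - r)])
    counts <- counts + shifted
  }
  dev <- abs(w_obs - tot / 2)
  s <- seq(0, tot)
  sum(counts[abs(s - tot / 2) >= dev - 1e-9]) / 2^n
}

#' Hydration-effect summary with exact signed-rank testing
#'
#' Assembles the per-hour hydration table: mean zero-pressure thickness,
#' loading-phase modulus at 15 mmHg and hysteresis across replicate eyes,
#' the percent change of each versus hour 0, and the exact Wilcoxon
#' signed-rank p-value comparing each hour to hour 0 (paired by eye).
#'
#' @param results A tibble with one row per eye and hour: columns `eye`,
#'   `hour`, `T0_um`, `E15_kPa`, `hysteresis_kPa`.
#' @return A `hydration_summary` tibble with one row per hour: means,
#'   percent changes (0 at hour 0) and p-values (`NA` at hour 0).
#' @export
hydration_summary <- function(results) {
  req <- c("eye", "hour", "T0_um", "E15_kPa", "hysteresis_kPa")
  miss <- setdiff(req, names(results))
  if (length(miss) > 0) {
    abort(paste0("results are missing column(s): ", paste(miss, collapse = ", ")))
  }
  hours <- sort(unique(results$hour))
  if (!0 %in% hours) abort("missing hour 0 (baseline) in the results.")
  if (length(hours) < 2) abort("need at least 2 hours of results including hour 0.")

  base <- results[results$hour == 0, ]
  base <- base[order(base$eye), ]
  out <- purrr::map_dfr(hours, function(h) {
    g <- results[results$hour == h, ]
    g <- g[order(g$eye), ]
    if (!identical(g$eye, base$eye)) {
      abort("each hour must contain the same replicate eyes as hour 0.")
    }
    p_of <- function(col) {
      if (h == 0) return(NA_real_)
      d <- g[[col]] - base[[col]]
      if (all(d == 0)) return(NA_real_)
      wilcoxon_signed_rank_exact(d)
    }
    tibble(
      hour = h,
      n_eyes = nrow(g),
      T0_um = mean(g$T0_um),
      E15_kPa = mean(g$E15_kPa),
      hysteresis_kPa = mean(g$hysteresis_kPa),
      hysteresis_mmHg = mean(g$hysteresis_kPa) / 0.1333224,
      T0_pct = percent_change(mean(base$T0_um), mean(g$T0_um)),
      E15_pct = percent_change(mean(base$E15_kPa), mean(g$E15_kPa)),
      hysteresis_pct = percent_change(mean(base$hysteresis_kPa), mean(g$hysteresis_kPa)),
      p_T0 = p_of("T0_um"),
      p_E15 = p_of("E15_kPa"),
      p_hysteresis = p_of("hysteresis_kPa")
    )
  })
  class(out) <- c("hydration_summary", class(out))
  out
}

#' Simulate a replicate-eye hydration study (noiseless analytics)
#'
#' Generates `n_eyes` jittered corneas with [simulate_eyes()], runs the
#' noiseless geometry + mechanics pipeline for every hydration hour, and
#' collects the per-eye measurands consumed by [hydration_summary()]:
#' zero-pressure thickness, loading modulus at 15 mmHg and loop hysteresis.
#'
#' @param hours Hydration hours (must include 0).
#' @param n_eyes Number of replicate corneas.
#' @param base Base [forward_params()].
#' @param rel_sd Between-eye relative jitter (see [simulate_eyes()]).
#' @param seed Integer seed.
#' @return A tibble with columns `eye`, `hour`, `T0_um`, `E15_kPa`,
#'   `hysteresis_kPa`.
#' @export
simulate_hydration_study <- function(hours = 0:4, n_eyes = 8,
                                     base = forward_params(),
                                     rel_sd = 0.03, seed = 42L) {
  eyes <- simulate_eyes(n_eyes, base = base, rel_sd = rel_sd, seed = seed)
  purrr::imap_dfr(eyes, function(par, i) {
    purrr::map_dfr(hours, function(h) {
      series <- simulate_geometry(pressure_schedule(hours = h), par)
      curves <- build_curves(series, mechanics_config(), B = par$B)
      hyst <- hysteresis(curves)
      tibble(
        eye = i, hour = h,
        T0_um = series$T_um[series$P_mmHg == 0 & series$phase == "loading"][1],
        E15_kPa = modulus_at(curves, P = 15, phase = "loading", hour = h),
        hysteresis_kPa = hyst$hysteresis_kPa[1]
      )
    })
  })
}
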