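#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

new_fit <- function(class, params, rss, fitted, residuals, data,
                    unidentifiable = character(0), converged = TRUE) {
  structure(
    list(
      params = params, rss = rss, fitted = fitted, residuals = residuals,
      data = data, unidentifiable = unidentifiable, converged = converged
    ),
    class = c(class, "oct_fit")
  )
}

#' @export
print.oct_fit <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1]))
  for (nm in names(x$params)) {
    cat(sprintf("  %-9s %.6g%s\n", nm, x$params[[nm]],
                if (nm %in% x$unidentifiable) " (unidentifiable)" else ""))
  }
  cat(sprintf("  rss       %.6g  (n = %d)\n", x$rss, length(x$fitted)))
  invisible(x)
}

#' @export
tidy.oct_fit <- function(x, ...) {
  tibble(
    term = names(x$params),
    estimate = unname(unlist(x$params)),
    unidentifiable = names(x$params) %in% x$unidentifiable
  )
}

#' @export
glance.oct_fit <- function(x, ...) {
  tibble(
    rss = x$rss, n = length(x$fitted),
    converged = x$converged,
    n_unidentifiable = length(x$unidentifiable)
  )
}

nls_controls <- function() {
  minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15, maxiter = 1024)
}

#' Fit the shifted power-law thickness-pressure relation
#'
#' Least-squares fit of `T = a - b * P^c` to a thickness series. The fit is
#' deterministic: it starts from `a0 = max(T)`, `c0 = 0.3` and `b0` solved
#' from the extreme points, with the exponent bounded to (0.05, 1) for
#' identifiability on short schedules. A constant series returns `b = 0`
#' with the exponent flagged unidentifiable.
#'
#' @param data A data frame (e.g. a `geometry_series`).
#' @param pressure,thickness Column names (tidy-eval) holding pressure in
#'   mmHg and thickness in um; defaults `P_mmHg`, `T_um`.
#' @return A `thickness_fit` object with params `a`, `b`, `c` and `rss`;
#'   see [tidy()] / [glance()].
#' @export
#' @examples
#' d <- dplyr::filter(simulate_geometry(pressure_schedule()), phase == "loading")
#' fit_thickness_power(d)
fit_thickness_power <- function(data, pressure = P_mmHg, thickness = T_um) {
  P <- dplyr::pull(data, {{ pressure }})
  T_ <- dplyr::pull(data, {{ thickness }})
  if (length(P) < 4) abort("need at least 4 points.")
  if (length(unique(P[P > 0])) < 3) abort("need at least 3 distinct positive pressures.")
  if (any(P < 0)) abort("pressures must be >= 0.")

  if (diff(range(T_)) < 1e-9 * max(1, abs(mean(T_)))) {
    a <- mean(T_)
    return(new_fit("thickness_fit",
      params = list(a = a, b = 0, c = NA_real_),
      rss = sum((T_ - a)^2), fitted = rep(a, length(T_)),
      residuals = T_ - a, data = tibble(P = P, T = T_),
      unidentifiable = "c"
    ))
  }

  a0 <- max(T_)
  c0 <- 0.3
  pmax_ <- max(P)
  b0 <- (a0 - T_[which.max(P)]) / pmax_^c0
  if (!is.finite(b0) || b0 == 0) b0 <- 1
  df <- data.frame(P = P, T = T_)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      T ~ a - b * P^c, data = df,
      start = list(a = a0, b = b0, c = c0),
      lower = c(a = -Inf, b = -Inf, c = 0.05),
      upper = c(a = Inf, b = Inf, c = 1),
      control = nls_controls()
    ),
    error = function(e) abort(paste0("fit failure: ", conditionMessage(e)))
  )
  cf <- coef(fit)
  fitted <- cf["a"] - cf["b"] * P^cf["c"]
  new_fit("thickness_fit",
    params = list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"])),
    rss = sum((T_ - fitted)^2), fitted = fitted, residuals = T_ - fitted,
    data = tibble(P = P, T = T_)
  )
}

#' Fit the linear radius-pressure relation
#'
#' Ordinary least squares line `R = intercept + slope * P`.
#'
#' @param data A data frame.
#' @param pressure,radius Column names (tidy-eval); defaults `P_mmHg`, `R_mm`.
#' @return A `radius_fit` object with params `intercept` (mm) and `slope`
#'   (mm/mmHg).
#' @export
fit_radius_linear <- function(data, pressure = P_mmHg, radius = R_mm) {
  P <- dplyr::pull(data, {{ pressure }})
  R <- dplyr::pull(data, {{ radius }})
  if (length(unique(P)) < 2) abort("need at least 2 distinct pressures.")
  fit <- lm(R ~ P)
  cf <- coef(fit)
  new_fit("radius_fit",
    params = list(intercept = unname(cf[1]), slope = unname(cf[2])),
    rss = sum(fit$residuals^2), fitted = unname(fit$fitted.values),
    residuals = unname(fit$residuals), data = tibble(P = P, R = R)
  )
}

#' Fit the saturating-exponential displacement-pressure relation
#'
#' Least-squares fit of `D = Dmax * (1 - exp(-P / Pc))`. Deterministic
#' initialisation: `Dmax0` slightly above the largest displacement and
#' `Pc0` from the pressure at half-saturation. A series of all-zero
#' displacements returns `Dmax = 0` with `Pc` flagged unidentifiable.
#'
#' @param data A data frame.
#' @param pressure,displacement Column names (tidy-eval); defaults
#'   `P_mmHg`, `D_um`.
#' @return A `displacement_fit` object with params `Dmax` (um), `Pc` (mmHg).
#' @export
fit_displacement_exponential <- function(data, pressure = P_mmHg,
                                         displacement = D_um) {
  P <- dplyr::pull(data, {{ pressure }})
  D <- dplyr::pull(data, {{ displacement }})
  if (length(P) < 3) abort("need at least 3 points.")

  if (max(abs(D)) < 1e-12) {
    return(new_fit("displacement_fit",
      params = list(Dmax = 0, Pc = NA_real_),
      rss = 0, fitted = rep(0, length(D)), residuals = rep(0, length(D)),
      data = tibble(P = P, D = D), unidentifiable = "Pc"
    ))
  }

  dmax0 <- max(D) * 1.05
  half <- dmax0 / 2
  above <- which(D >= half)
  p_half <- if (length(above) > 0) P[above[1]] else stats::median(P)
  pc0 <- max(p_half, 1e-3) / log(2)
  df <- data.frame(P = P, D = D)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      D ~ Dmax * (1 - exp(-P / Pc)), data = df,
      start = list(Dmax = dmax0, Pc = pc0),
      lower = c(Dmax = 0, Pc = 1e-6),
      control = nls_controls()
    ),
    error = function(e) abort(paste0("fit failure: ", conditionMessage(e)))
  )
  cf <- coef(fit)
  fitted <- cf["Dmax"] * (1 - exp(-P / cf["Pc"]))
  new_fit("displacement_fit",
    params = list(Dmax = unname(cf["Dmax"]), Pc = unname(cf["Pc"])),
    rss = sum((D - fitted)^2), fitted = fitted, residuals = D - fitted,
    data = tibble(P = P, D = D)
  )
}
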