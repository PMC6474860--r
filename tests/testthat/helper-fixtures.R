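# Compact optics for unit tests: same physics, ~6x fewer pixels than the
# bench-scale default so per-test renders stay fast.
small_optics <- function(...) {
  args <- utils::modifyList(
    list(axial_um_per_px = 3, lateral_um_per_px = 20,
         lateral_fov_mm = 6.4, axial_fov_um = 2900),
    list(...)
  )
  do.call(optics_config, args)
}

# analytic anterior-surface optical depth for a rendered state, evaluated at
# the trace's lateral positions (image frame, apex at the image centre)
true_anterior_um <- function(state, traces, optics) {
  x <- traces$x_um - mean(range(traces$x_um))
  R_um <- state$R_mm * 1000
  optics$apex_offset_um - state$D_um + (R_um - sqrt(R_um^2 - x^2))
}

# build a surface_pair directly (physical depths) for geometry unit tests
make_traces <- function(x_um, anterior_um, posterior_um,
                        depths = "physical", n_group = 1.389) {
  out <- tibble::tibble(
    column = seq_along(x_um), x_um = x_um,
    anterior_um = anterior_um, posterior_um = posterior_um,
    quality = "detected"
  )
  attr(out, "depths") <- depths
  attr(out, "n_group") <- n_group
  class(out) <- c("surface_pair", class(out))
  out
}

# exact polygon area of a non-self-intersecting loading/unloading loop
# (shoelace formula); equals the integral of |sigma_l - sigma_u| when the
# curves do not cross
shoelace_loop_area <- function(loading, unloading) {
  x <- c(loading$epsilon, rev(unloading$epsilon))
  y <- c(loading$sigma_kPa, rev(unloading$sigma_kPa))
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# brute-force exact two-sided signed-rank p-value: literal loop over all
# 2^n sign assignments of the midranks
wilcoxon_brute_force <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  tot <- sum(r)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(abs(w_all - tot / 2) >= abs(w_obs - tot / 2) - 1e-9)
}
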