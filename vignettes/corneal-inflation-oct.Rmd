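---
title: "Corneal inflation elastography from synthetic LF-OCT B-scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corneal inflation elastography from synthetic LF-OCT B-scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(octinflate)
library(dplyr)
```

# The measurement problem

In an ex-vivo corneal inflation test, an excised cornea is clamped at the
limbus in an artificial anterior chamber and a hydraulic pressure (emulating
intraocular pressure, IOP) is applied to its posterior surface over a
loading/unloading cycle, here 0–60 mmHg in 5 mmHg steps with extra stops at
0 and 2 mmHg. Optical coherence tomography images the corneal cross-section
at every step; from the segmented anterior and posterior boundaries one
measures the apex thickness $T$, the anterior radius of curvature $R$ and
the apex displacement $\Delta D$, and from those the elastic properties of
the tissue.

`octinflate` implements this analysis end to end and, because inflation
data sets of this kind are rarely deposited, pairs it with a forward model
that simulates the experiment: ground-truth geometry over a pressure and
hydration schedule, and synthetic B-scans rendered from that geometry. Every
stage of the analysis can therefore be validated against a known truth.

# The thin-walled-sphere model

The mechanical model treats the pressurised central cornea as a thin
spherical shell clamped at a rigid boundary of base width $B = 5.25$ mm.
At each pressure step:

* circumferential (hoop, Laplace-law) stress
  $\sigma = \dfrac{P\,R}{2\,T}$ (kPa, with $P$ converted at
  0.1333224 kPa/mmHg and $T$ in mm);
* volumetric strain of the parabolic cap under the cornea,
  $\varepsilon = (V - V_o)/V_o$ with $V = \tfrac{\pi}{2} H B^2$, where $H$
  is the interior apical height and the subscript $o$ marks the reference
  state (loading at 2 mmHg, where the cornea first holds a stable
  curvature). The printed literature form of this ratio sometimes carries
  the opposite sign, $(V_o - V)/V_o$; we use the inflation-positive sign so
  the modulus below is positive, and the magnitudes are identical;
* tangent elastic modulus
  $E_c = 3(1-\nu)\,\sigma/\varepsilon$ with Poisson's ratio $\nu = 0.40$
  (slightly compressible tissue).

The cap height is updated from the measured quantities as
$H = H_o + \Delta D/1000 + (T_o - T)/1000$ (mm): the posterior apex rises by
the anterior apex rise plus the apical thinning. $H_o$ enters only as a
strain normalisation; it is a measured/configured input that defaults to
3.0 mm.

Corneal hysteresis is the area between the loading and unloading branches
of the stress–strain curve: both branches are linearly interpolated onto a
uniform strain grid over the intersection of their strain ranges (512
points by default, no extrapolation) and the trapezoidal integral of
$|\sigma_{load} - \sigma_{unload}|$ is reported in kPa and, divided by the
pressure conversion factor, in mmHg.

# The synthetic-data generator

## Geometry laws

The forward model is anchored to empirical pressure laws for fresh porcine
corneas:

* thickness (µm): $T(P) = s(h)\,(1085.5 - 57.3\,P^{0.265})$;
* anterior apex radius (mm): $R(P) = 8.448 - 0.005\,P$;
* apex displacement (µm): $D(P) = D_{max}(1 - e^{-P/P_c})$ with
  $P_c = 12$ mmHg. Only the qualitative form (a saturating exponential with
  most of the change below 20 mmHg) is constrained by observation, so the
  saturating exponential with a 12 mmHg constant is a package design
  choice. The default $D_{max}$ is set so the displacement gain between the
  2 mmHg reference and 60 mmHg equals the reported maximum of 143 µm, which
  gives $D_{max} = 143/(e^{-2/12} - e^{-60/12}) \approx 170.3$ µm.

```{r}
forward_params()
```

## Unloading and the hysteresis loop

No constitutive unloading law is available, so the generator opens the loop
with a single pressure-lag factor $\lambda$: unloading states evaluate the
thickness and displacement laws at the effective pressure $P(1+\lambda)$,
leaving the radius shared between phases (radius differences between phases
are reported as insignificant). The lag keeps the unloading cornea thinner
and more displaced than the loading cornea at the same pressure, which is
the observed asymmetry, and gives monotone control of the loop area
(`calibrate_lam_to_hysteresis()`).

The lag model has a ceiling: the loop area cannot exceed the area under the
loading stress–strain curve (about 4 mmHg equivalents under the default
geometry, reached near $\lambda \approx 5$, beyond which the shrinking
strain-range overlap reduces the integrable area again). The ~10.5 mmHg
loop reported for fresh porcine corneas is therefore not reachable inside
this forward model at the calibrated geometry; the default $\lambda = 0.25$
produces a realistic open loop of ~1.2 mmHg, and the calibration helper
fails loudly, reporting the achievable ceiling, when asked for more. None
of the quantitative round-trip checks depend on the loop area.

## Hydration swelling

Immersion in PBS swells the cornea. Swelling is modelled as a multiplicative
factor on the whole thickness law,
$s(h) = s_\infty - (s_\infty - 1)e^{-rh}$, anchored at two reported points:
$s(1) = 1.06$ (a 6 % thickness gain after one hour) and a plateau solved so
the hour-4 zero-pressure thickness equals the reported maximum of
1222.47 µm, i.e. $s(4) = 1222.47/1085.5$. Solving both constraints gives
$s_\infty \approx 1.142$, $r \approx 0.55\,h^{-1}$. Swelling leaves the
displacement and radius laws untouched; consequently the generator does
*not* emulate the reported stiffening (and hysteresis growth) of swollen
corneas, which in the real tissue comes from hydration-induced changes in
the collagen network rather than from geometry alone. Hydration-time
statistics on simulated data should therefore only be read as exercising
the machinery (percent changes, exact signed-rank tests), not as
reproducing the physiology of modulus growth.

## Rendering

`render_bscan()` converts a geometry state into a calibrated grayscale
B-scan the way the instrument would see it:

* the anterior surface is a circular arc of radius $R$ whose apex sits at a
  fixed datum minus the displacement $D$ (the apex moves toward the
  instrument as pressure rises);
* below the anterior surface the image is laid out in *optical* path
  length: the anterior–posterior gap equals $n_g T$ with group refractive
  index $n_g = 1.389$, and an epithelium interface with distinct
  reflectivity sits at $n_g \times 100$ µm below the anterior surface (the
  100 µm epithelium is cosmetic, there to make segmentation prove it can
  ignore interior interfaces);
* bands are rasterised with area-weighted (sub-pixel) edges, blurred
  axially with a Gaussian PSF of FWHM 3.5 µm, and multiplied by log-normal
  speckle of scale 0.3 (mean-preserving, `exp(sigma * Z - sigma^2/2)`).

Defaults are 2 µm/px axial sampling in air, 10 µm/px lateral sampling and
an 8 mm × 3.3 mm field, i.e. ~1650 × 800 px per scan — chosen so the PSF
and the central 3 mm analysis window are well sampled at desk scale. All
randomness flows from one integer seed; per-scan seeds are derived as
`seed + scan index`, so stacks are bit-reproducible.

The renderer is geometric: it draws surfaces, blur and speckle, and makes
no attempt at wave-optics image formation (no interferogram or spectral
synthesis), nor at scleral deformation — the boundary is rigid by
assumption.

# Segmentation and refraction correction

Boundary detection is fully automated (the field's codes are often
semi-automated, but manual seeding is neither reproducible nor testable):
per image column, the intensity profile is boxcar-smoothed (3 px), its
depth gradient taken, and local maxima of the gradient magnitude above an
adaptive threshold (median + 4 MAD of that column's gradient magnitude)
located. The *first* such peak is the anterior boundary and the *last* one
is the posterior boundary — a deliberately asymmetric rule that is immune
to speckle-induced interior peaks, because those always lie between the
two surfaces. Peak positions are refined to sub-pixel precision with a
three-point parabolic fit. Traces are then median-filtered across columns
(width 11) and screened against a local quadratic (loess, degree 2, span
0.15) fit; columns deviating by more than 3 MAD are flagged and replaced
by interpolation. Fewer than 50 % of columns detected raises a
segmentation-failure error.

`correct_refraction()` converts optical to physical depths: the anterior
trace travels through air and is unchanged; the anterior-to-posterior
optical gap is divided by $n_g$ per column. Lateral ray bending at the
anterior surface is ignored — near the apex incidence is near-normal and
the error is second order; this is an approximation, stated as such.

Geometric measurands then follow on the corrected traces, all on the
central 3 mm window centred on the apex column: mean per-column axial gap
(thickness; axial rather than surface-normal pachymetry, a second-order
difference at the apex), algebraic least-squares (Kåsa) circle radius, and
the apex depth taken from the fitted circle (`cz - r`), which averages
boundary noise over all ~300 window columns and makes displacement
differences reproducible to well under a micrometre even with speckle.

# Numerical choices and tolerances

* Empirical-law fitting uses Levenberg–Marquardt least squares
  (`minpack.lm::nlsLM`) with deterministic initialisation (no random
  restarts): for the thickness law $a_0 = \max T$, $c_0 = 0.3$, $b_0$
  solved from the extreme points, with the exponent bounded to (0.05, 1)
  to prevent degenerate $b$/$c$ exchanges on 14-point schedules; for the
  displacement law $D_{max,0}$ slightly above the largest displacement and
  $P_{c,0}$ from the half-saturation pressure. Constant series return the
  degenerate fit with the unidentifiable parameter flagged rather than
  erroring.
* The modulus calibration (`calibrate_to_modulus()`) adjusts $D_{max}$
  alone by bisection (geometric midpoint, bracket widened geometrically
  until the target is straddled) against the noiseless analytic pipeline,
  to 0.1 % relative.
* The exact Wilcoxon signed-rank test enumerates the $2^n$ sign
  assignments of the (doubled, hence integer) midranks via convolution;
  zero differences are dropped first, and the two-sided p-value is
  $P(|W - E W| \ge |w_{obs} - E W|)$ under the symmetric null. It is exact
  for $n \le 20$, covering the $n = 8$ designs this assay uses.
* Hysteresis integration: trapezoid on a uniform 512-point strain grid;
  on smooth loops doubling the grid changes the area by < 0.1 %, and on
  piecewise-linear loops with grid-aligned knots it agrees with the exact
  shoelace polygon area to 1e-9 relative (both are test invariants).
* Ties in gradient peaks resolve shallow-first for the anterior surface
  and deep-first for the posterior (first/last peak rule); apex-column
  ties resolve to the candidate nearest the trace centre.

# What the tests do and do not show

The test suite validates the pipeline against the generator's known truth:
noiseless round trips recover thickness within the 2.2 µm instrument-level
repeatability, radius within 1 % and displacement within one axial pixel;
default-speckle round trips recover the 60 mmHg thickness, the 143 µm
displacement gain, the hour-4 swollen thickness and the 6 % first-hour
swelling within 0.5 %. Problem sizes are the bench-scale defaults: 27-scan
cycles of ~1650 × 800 px images for the round-trip checks, with smaller
6.4 mm fields in unit tests.

Because the phantoms are generated by the package's own forward model,
these tests demonstrate *internal* consistency — segmentation, refraction
correction, geometry and mechanics invert the renderer faithfully — not
performance on real LF-OCT images, whose speckle statistics, motion
artefacts, tilt and irregular surfaces the geometric renderer does not
emulate. The renderer's uniform axial optical gap also means axial and
normal pachymetry coincide by construction.

# A worked run

```{r, fig.width = 7, fig.height = 3}
params <- forward_params()
schedule <- pressure_schedule()
truth <- simulate_geometry(schedule, params)
curves <- build_curves(truth, mechanics_config(), B = params$B)
mechanics_summary(curves)
autoplot(curves)
```

The full image-based pipeline, including rendering and segmentation, runs
through `run_pipeline()`; see the README for a complete example with its
printed output.

# Known limitations

* The thin-shell closed form is the model boundary: no finite-element or
  fibril-level constitutive modelling, no regional thickness variation
  (the apex-only, homogeneous-thickness assumption is retained).
* Hydration affects geometry only; modulus/hysteresis growth with swelling
  is outside the generator (see above).
* The pressure-lag loop caps the achievable hysteresis well below the
  value reported for fresh tissue.
* Segmentation is column-wise; there is no graph-based global
  optimisation, which real, lower-quality images might need.
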