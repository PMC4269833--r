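---
title: "Modelling and quantifying chiral cortical flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and quantifying chiral cortical flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiralflow)
```

## The physical picture

The actomyosin cortex of the early *C. elegans* embryo is a thin
contractile layer between membrane and cytoplasm. Myosin motors pull and
twist actin filaments, so at the coarse-grained scale the material carries
both an active tension $T$ and an active torque density $\tau$. Gradients
of $T$ along the anteroposterior (AP) axis drive flow along the axis;
gradients of $\tau$ drive flow orthogonal to it, giving the cortex its
measurable chirality: the anterior and posterior halves counter-rotate.

Treating the cortex as a thin film of an active chiral fluid, azimuthally
symmetric around the AP axis, the two in-plane velocity components obey

$$\ell\,\partial_x^2 v_x - v_x/\ell = \partial_x T, \qquad
  \tfrac{\ell}{2}\,\partial_x^2 v_y - v_y/\ell = \partial_x \tau,$$

with $T = \alpha I(x)$ and $\tau = \beta I(x)$ proportional to the myosin
fluorescence intensity $I$. The model's assumptions, in order of
importance:

* **Azimuthal symmetry.** $I$, $v_x$ and $v_y$ depend on $x$ only. The
  package's `half_intensity_difference()` with the
  `"top-bottom-posterior"` split is the empirical check for this
  assumption on image data.
* **Linear myosin coupling.** $T$ and $\tau$ are linear in $I$. With
  nonlinear or independently regulated couplings the fitted $c$ is an
  effective, embryo-averaged chirality index; the package deliberately
  fits only the linear form.
* **Overdamped, steady flow per frame.** Inertia is negligible; each
  velocity profile is treated as a steady response to the instantaneous
  myosin distribution.

The viscosity $\eta$ and friction $\gamma$ never appear separately once
the equations are divided by $\gamma$: only $\ell = \eta/\gamma$ and the
velocity-unit couplings $\alpha, \beta$ are identifiable, which is why
`model_params` stores exactly those three numbers plus the derived
chirality index $c = \beta/\alpha$. (One printed account of the index
inverts the ratio; the definition $c = \tau/T = \beta/\alpha$ is the one
used consistently and is what this package implements.)

Note the factor $\tfrac12$ on the chiral viscous term, which we keep
exactly as the theory states it: the axial component is screened over
$\ell$ and the chiral component over $\ell/\sqrt2$. Both decay lengths are
verified by log-slope fits in the test suite (2% tolerance over
$\ell \in \{8, 16, 32\}\,\mu m$).

## Sign conventions and the observed handedness

Under the sign convention of the printed equations, the interior solution
is approximately $v_x \approx -\ell\,\partial_x(\alpha I)$ away from
boundaries. Reproducing the observed phenomenology — AP flow directed
*toward* the myosin-rich anterior, flow toward a myosin stripe from both
sides, and a negative counter-rotation velocity $v_c$ with positive
chirality index — therefore requires $\alpha < 0$ and $\beta < 0$
(leaving $c = \beta/\alpha > 0$). The synthetic generator's default truth
is `model_params(16, -10, -5.8)` for this reason; the fit itself is
sign-agnostic.

A second geometric subtlety: $v_c$ compares posterior bins 13–16 with
anterior bins 3–6, which mirror each other about mid-embryo. A myosin
boundary exactly at mid-embryo produces a chiral flow profile symmetric
between the two windows and $v_c = 0$ identically. The generator places
the sigmoid boundary at 60% egg length — in polarized zygotes the
anterior myosin domain extends past the midpoint — which breaks the
symmetry and yields $v_c < 0$, as observed.

## Solving the flow equations

`solve_axial_flow()` and `solve_chiral_flow()` discretise each equation
with second-order central differences on a uniform grid spanning the
intensity profile's domain (201 nodes by default; the tridiagonal system
is solved by the Thomas algorithm). Numerical choices:

* **Source term.** $\partial_x(\alpha I)$ is evaluated by central
  differences of the coupled intensity on the solver grid, with one-sided
  second-order stencils at the two boundary nodes.
* **Resampling.** The 18-bin measured intensity is interpolated onto the
  solver grid with a shape-preserving monotone cubic
  (`splinefun(method = "monoH.FC")`); an unconstrained cubic can
  overshoot between coarse bins and fabricate spurious tension gradients.
  Linear interpolation is available via `solver_config(interp =
  "linear")` — and is what makes the forward map exactly linear in $I$,
  since the monotone scheme is (by design) not a linear map of the bin
  values.
* **Boundary conditions.** Dirichlet, equal to the two extreme points of
  the measured velocity profile (zero for pure simulation). The measured
  endpoints are used raw, without smoothing. No-flux boundaries are
  deliberately not offered.
* **Verification.** The discretisation is checked against an
  infinite-domain Green's-function quadrature (narrow Gaussian source in
  a 200 μm domain, < 0.5% relative $L_2$), against a dense brute-force
  solve of the same linear system (machine precision), and by grid
  self-convergence (201 vs 2001 nodes, < 0.1%).

The default synthetic embryo is 50 μm long (typical zygote length) with
18 AP bins, a 30 μm footprint, 1 μm vector spacing and ~0.5 μm/min
per-vector velocity noise — the scale suggested by SEM bars on measured
profiles.

## Fitting $\ell$, $\alpha$, $\beta$

`chiral_fit()` minimises the summed squared residuals of both velocity
components over interior bins; the endpoints are imposed as boundary
conditions and are therefore excluded from the residual (16 + 16 = 32
observations for 18-bin profiles). The $v_x$ and $v_y$ residuals carry
equal weight by default (`weight_vy` changes this).

Because the model is linear in $\alpha$ and $\beta$ for fixed $\ell$, the
3-parameter problem is profiled: an outer one-dimensional `optimize()`
over $\ell$ (default search interval 0.05–5 × domain length) with the
inner $(\alpha, \beta)$ subproblem solved exactly by linear least squares
at every step, followed by a Nelder–Mead polish of the full objective.
The polish is bounded to the $\ell$ interval: on noisy replicates the
objective can be nearly flat in $\ell$ at large values, and an unbounded
simplex occasionally wanders off to meaninglessly large lengths.

Uncertainties come from the Hessian of $\tfrac12 RSS$ at the optimum,
computed by central finite differences (relative step $10^{-4}$;
halving the step changes the standard errors by well under 1%):
$\mathrm{cov} = s^2 H^{-1}$ with $s^2 = RSS/(n_{obs} - 3)$. The standard
error of $c = \beta/\alpha$ follows by first-order propagation including
the $(\alpha, \beta)$ covariance. Degenerate cases are handled
explicitly: all-zero velocity input leaves $\ell$ unidentifiable and is
flagged (`identifiable = FALSE`, `NaN` errors); a non-positive-definite
Hessian (a genuinely flat direction, which at 10% velocity noise happens
in roughly a tenth of replicates) reports `NaN` standard errors with a
warning rather than a fabricated number. Monte-Carlo calibration in the
test suite (100 replicates at 10% of peak speed) checks that the mean
reported error of $c$ agrees with the empirical scatter within a factor
of two and that the bias of $c$ stays below 0.05.

Summary intervals follow the convention "error of the mean at 99%
confidence" = 2.576 × SEM (normal approximation); `summary()` and
`confint()` take a `level` argument.

## Flow statistics

`bin_velocity_profile()` divides the AP extent into 18 equal bins
(1-based indices, so the anterior window is "bins 3–6" and the posterior
"bins 13–16" exactly as the regions are named), restricts vectors to a
~13 μm stripe that we centre on the embryo midline (the centring is a
package choice; the stripe height is the stated one), and averages each
component per bin. Averaging order matters and is fixed: per-frame
profiles → time average within embryo → unweighted mean across embryos,
with SEM across embryos. For $v_c$ histograms, frames are pooled across
embryos instead — the two procedures intentionally differ, mirroring how
the respective measurements are defined.

`counter_rotation_velocity()` is the posterior-minus-anterior mean of the
binned $v_y$; it is exactly invariant under uniform $v_y$ offsets,
exactly sign-flipped by a $y$-mirror of the field, and linear in velocity
rescaling (all asserted in tests). The 4-cell variant projects velocities
on the cleavage-plane direction and averages within a slab on each side
of the plane; "a box of width 5 μm close to the cleavage plane" is
interpreted as a 2.5 μm slab per side (`box_halfwidth = 2.5`), together
spanning 5 μm around the plane. Left/right are defined looking along the
plane direction, and the statistic is rotation-invariant by construction.

`compare_conditions()` wraps the two-sided Wilcoxon rank-sum test (exact
for small samples, normal approximation with continuity correction
otherwise) at the level appropriate to the comparison: 0.01 for 1-cell
flow statistics, 0.05 for skew comparisons.

Outliers in per-video statistics are *flagged* (robust z-score > 3.5 on
the scaled MAD) but never removed automatically: exclusions in this kind
of analysis follow qualitative criteria (sideways polarization, whole-body
rotation) that no automatic rule reproduces faithfully, so removal
requires an explicit `exclude` entry in the configuration.

## Skew angles

`build_body_frame()` constructs the right-handed orthonormal triad:
AP from the anterior to the posterior pole; DV as the component of the
EMS nucleus position orthogonal to the AP axis (foot-of-perpendicular
reference point), pointing ventrally toward EMS; LR $=$ AP $\times$ DV.
An EMS position collinear with the AP axis is an error, not a silent
default.

`skew_angle()` measures the reorientation of a division axis between the
beginning and end of telophase in the AP–LR plane (dorsal view), the
DV–LR plane (anterior view) or as the unsigned 3D angle. Since reported
skew values are magnitudes, the sign convention is a package choice,
documented here: positive means clockwise for a viewer looking along +DV
(dorsal view) or along +AP (anterior view); via the scalar triple product
this is $\operatorname{atan2}((u \times w)\cdot \hat n,\ u\cdot w)$ with
$\hat n$ the plane normal. A rotation constructed about the DV axis is
recovered exactly in the AP–LR plane with zero DV–LR component; mirror
reflection through the AP–DV plane flips planar signs; rigid motions of
all inputs change nothing (all asserted at machine precision in tests).

## Foci size

`spatial_autocorrelation()` estimates the mean-subtracted,
variance-normalised spatial autocorrelation of an image or rectangular
ROI by zero-padded FFT, divides by the per-lag overlap count (the
unbiased estimator), and radially averages — the texture is treated as
isotropic, so the 2D correlation is collapsed to one radial curve in
physical units (whether the original analysis was 1D or radial is not
stated; radial averaging uses all pixel pairs and is the more robust
choice).

`foci_size()` fits $A e^{-r/\lambda} + b$ over lags 0.5–5 μm by default,
excluding the zero-lag point (pixel-noise spike). The floating baseline
$b$ is a deliberate numerical choice: subtracting the sample mean of a
finite window removes fluctuations at the window scale and shifts the
whole empirical curve downward, and without $b$ the decay length of
textures with $\lambda \gtrsim 2\,\mu m$ is underestimated severalfold.
The decay length $\lambda$ — the characteristic foci size — is reported
per frame, averaged within an embryo over the analysis window (the first
75 s of flow in the original design), then ensemble-averaged
(`foci_size_series()`). A non-decaying curve, or one whose fitted decay
does not exceed twice the residual scatter, is flagged as non-converged
instead of returning a number.

Recovery checks use `make_correlated_image()`, a Gaussian random field
with exponential covariance synthesised by spectral filtering. The test
conditions are 256² px at 0.3 μm/px — a 77 μm field — with six frames
per condition: estimating a correlation length within 10% needs a field
many times larger than $\lambda$ (a 25.6 μm field cannot support
$\lambda = 4\,\mu m$ at that accuracy) plus per-frame averaging, exactly
as the real analysis averages frames. Under these conditions
$\lambda \in \{1, 2, 4\}\,\mu m$ is recovered within 10%.

## What the synthetic data do and do not emulate

The generators (`synthetic_spec()` and friends) produce: smooth
anterior-high sigmoid and cleavage-furrow stripe intensity profiles;
velocity profiles and 2D vector fields whose expectation is exactly the
forward model at known $(\ell, \alpha, \beta)$, with i.i.d. Gaussian
per-sample noise; images with a prescribed correlation length; and
nuclei/pole configurations rotated by a known skew about a chosen body
axis. Every generator is byte-identical under a fixed seed. Vector fields
tile each AP bin with its bin value, so that binning recovers the
generating profile exactly at zero noise — a deliberate testability
choice over smooth within-bin variation.

They do **not** emulate: spatially correlated PIV noise (real PIV errors
correlate over interrogation windows), intensity-dependent noise,
embryo-shape masks and segmentation artefacts, drift, out-of-plane
motion, or deviations from the model's own equations. Passing round-trip
tests therefore demonstrates the correctness and calibration of the
implementation under the model's assumptions — not that the model is the
right description of any particular embryo.

## Problem sizes and runtime

The test suite and the acceptance script are sized for a laptop-class
single CPU: 201–4001 solver nodes, 18-bin profiles, 100-replicate
Monte-Carlo calibration, six 256² px images per correlation length, and
synthetic cohorts of 2–5 embryos × 4–30 frames. The full suite runs in
well under a minute; `scripts/acceptance.R` in a few seconds.

## Known limitations

* The model is 1D (azimuthally averaged); no 2D-on-surface solving.
* $\eta$ and $\gamma$ are not separately identifiable by design.
* The fit assumes homoscedastic residuals across bins and equal $v_x$ /
  $v_y$ weighting unless reweighted.
* With noisy short profiles $\ell$ can be weakly identified; the package
  reports the flat-direction cases honestly (`NaN` standard errors)
  rather than regularising them away.
* AP alignment of the field with the image x-axis is assumed; alignment
  detection is out of scope.
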