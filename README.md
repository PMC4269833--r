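# chiralflow

Quantification of chiral actomyosin cortical flow in early *C. elegans*
embryos, built around a thin-film active chiral fluid model of the cell
cortex.

## The problem

During polarization of the *C. elegans* zygote the actomyosin cortex flows
along the anteroposterior (AP) axis. On top of this axial flow the anterior
and posterior halves of the cortex counter-rotate about the AP axis — a
chiral motion, quantified by the counter-rotation velocity
*v*<sub>c</sub> = ⟨*v*<sub>y</sub>⟩<sub>P</sub> − ⟨*v*<sub>y</sub>⟩<sub>A</sub>,
the difference of the mean orthogonal velocity between posterior and
anterior regions. The package is for researchers who have
particle-image-velocimetry (PIV) velocity fields, AP-binned myosin
intensity profiles, 3D nuclei/pole coordinates and fluorescence images of
the cortex, and want to (i) fit the physical model that links myosin to
flow and (ii) compute the accompanying statistics: binned flow profiles,
*v*<sub>c</sub> at the 1- and 4-cell stages, division-axis skew angles and
myosin foci sizes.

## The model

The cortex is a thin film of an active chiral fluid. Myosin generates an
active tension *T* and an active torque density *τ*, both proportional to
the measured myosin intensity: *T* = *αI*(*x*), *τ* = *βI*(*x*). Under
azimuthal symmetry the AP velocity *v*<sub>x</sub> and the orthogonal
(chiral) velocity *v*<sub>y</sub> obey

    ℓ ∂²ₓ vx − vx/ℓ = ∂ₓ(αI)
    (ℓ/2) ∂²ₓ vy − vy/ℓ = ∂ₓ(βI)

where ℓ = η/γ is the hydrodynamic length over which flow is screened by
friction with membrane and cytoplasm. Tension and torque are carried in
velocity units (the physical stress divided by γ), so the model has
exactly three identifiable parameters: ℓ, α and β. The chirality index
*c* = *τ*/*T* = *β*/*α* measures how much motor activity goes into torque
relative to tension. `chiral_fit()` solves the two boundary-value problems
with a finite-difference scheme (boundary velocities taken from the two
extreme points of the measured profiles), performs the least-squares fit
of both solutions to the measured velocity profiles, and derives standard
errors from the curvature of the residual at the optimum.

## Worked example

All inputs can be synthesised with known ground truth (here: ℓ = 16 μm,
c = 0.58, per-vector noise 0.5 μm/min, 4 embryos × 20 frames):

```r
library(chiralflow)

spec <- synthetic_spec(noise_sd = 0.3, n_frames = 20, n_embryos = 4,
                       seed = 11)
dir <- tempfile()
write_synthetic_dataset(spec, dir)

report <- run_onecell_analysis(list(
  piv_files      = list.files(dir, "^piv_", full.names = TRUE),
  intensity_file = file.path(dir, "intensity.csv"),
  out_dir        = file.path(dir, "out")))
report$fit
#> Active chiral fluid model fit
#>   ell   =    15.97 +/- 0.072 um
#>   alpha =      -10 +/- 0.00731
#>   beta  =   -5.806 +/- 0.00808
#>   c     =   0.5803 +/- 0.00105
#>   RSS = 0.0006844 on 32 observations
```

The fitted hydrodynamic length (15.97 ± 0.07 μm) and chirality index
(0.580 ± 0.001) recover the generating values; `report$vc$summary` gives
the per-frame counter-rotation velocity pooled across embryos
(−0.67 ± 0.01 μm/min here — negative, i.e. the handedness seen in
unperturbed embryos). `plot(report$fit)` overlays the model profiles on
the binned data; `run_fourcell_analysis()` covers the 4-cell stage
(cleavage-plane *v*<sub>c</sub>, skew angles from labeled nuclei/pole
points, robust outlier flags); `spatial_autocorrelation()` + `foci_size()`
estimate myosin foci sizes from images.

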