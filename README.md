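# contourdyn

Quantitative analysis of single-cell adhesion, shape dynamics and motility
from label-free time-lapse microscopy of cells on ligand-functionalized
supported lipid membranes.

Cells adhering to such surfaces (imaged e.g. by reflection interference
contrast microscopy, where the adhesion footprint appears dark on a bright
background) change shape slowly and stochastically. The package extracts
the statistical structure hidden in that noise:

* **Segmentation** — background subtraction, Otsu binarization,
  morphological closing and hole filling turn each frame into an adhesion
  footprint mask; contours are traced sub-pixel, with area *A*, perimeter
  *L* and the center of mass per frame.
* **Shape descriptors** — circularity *4πA/L²* (1 for a circle) and
  elongation, the minor/major principal-axis ratio of the footprint's
  second area moments; cohort tables with mean ± sample SD.
* **Polar shape fluctuations** — the core statistic. Each contour is
  reduced to a polar profile *r(θ, t)* about its center (θ = 0 is the
  laboratory vertical, counterclockwise) and to the fluctuation
  amplitude map

  ΔR(θ, t) = r(θ, t) − R̄(t),

  with R̄(t) the angular mean radius of frame *t*. The normalized
  spatio-temporal autocorrelation

  G(Δθ, Δt) = ⟨ΔR(θ, t) · ΔR(θ + Δθ, t + Δt)⟩ / ⟨ΔR²⟩,

  averaged over all angles (periodic in Δθ) and all overlapping frame
  pairs, exposes the geometry of the dynamics: a *k*-fold symmetric cell
  gives *k* angular maxima spaced 360°/*k* apart, rigid rotation tilts the
  peak ridge with slope ω, and an elongate–round–re-elongate sequence
  shifts the peaks by 90°.
* **Motility** — center-of-mass trajectories, mean speed ⟨v⟩ from
  displacements sampled every 30 min (µm/h), and the joint distribution of
  contour deformation and motility direction. Its motion-axis marginal
  detects the symmetry break of polarized migration: a sub-peak displaced
  from zero by the protrusion size in the direction of motion.
* **Synthetic generator** — seeded, fully parameterized contour series
  (Fourier deformation modes, rigid rotation, smooth radial noise,
  persistent-random-walk translocation, motion-aligned protrusion),
  rendered image stacks and population adhesion kinetics. Every analysis
  stage is testable against known ground truth; all generator laws are
  synthetic stand-ins and are documented as such.
* **Surface design** — mean spacing of biotin-anchored ligands in a
  supported membrane, ⟨d⟩ = √(A_lipid/χ), and its inverse.

## Worked example

```r
library(contourdyn)

## a rotating three-fold-symmetric cell, 200 frames at 10 min
p <- cell_sim_params(base_radius = 12,
                     fourier_modes = data.frame(k = 3, a = 0.3, phase_deg = 0),
                     rotation_rate = 0.2, mode_noise_sd = 0.5, seed = 1)
cell <- simulate_cell(p, n_frames = 200, frame_interval = 10)
cell
#> <contour_series> 200 frames (200 with a cell), t = 0.0..1990.0 min
#>   area 467.1-480.8 um^2, mean perimeter 90.4 um

corr <- autocorrelation(amplitude_map(cell))
locate_peaks(corr, at_lag_min = 0)
#> [1] -120    0  120
ridge_slope(corr, max_lag_min = 250)$slope_deg_min
#> [1] 0.2
```

The three zero-lag maxima at −120°, 0°, +120° are the signature of the
three-fold shape, and the ridge slope recovers the configured rotation
rate of 0.2 deg/min exactly.

```r
## a polarized migrating cell with an 8 um motion-aligned protrusion
pm <- cell_sim_params(base_radius = 12, mode_noise_sd = 0.5, speed = 5,
                      persistence_time = 3000, protrusion_amplitude = 8,
                      protrusion_alignment = 1, seed = 11)
mig <- simulate_cell(pm, n_frames = 120, frame_interval = 10)
tr  <- track_centers(mig)
mean_velocity(tr, dt_min = 30)$mean_um_h
#> [1] 4.99
pdf <- deformation_direction_pdf(mig, tr)
symmetry_break_offset(pdf)
#> [1] 7.5
```

The mean speed recovers the configured 5 µm/h, and the deformation
marginal shows the off-center sub-peak of directed migration within one
1-µm bin of the planted 8-µm protrusion (the measured mode sits at the
bump height minus its angular mean, ≈ 7.3 µm).

```r
surface_design_table(c(0.005, 0.02, 0.1))
#>     chi mean_distance_nm
#> 1 0.005        10.954451
#> 2 0.020         5.477226
#> 3 0.100         2.449490
```

`run_pipeline()` chains all stages (TIFF stack or contour CSV in; CSV
maps, tables, trajectory and a summary JSON out) under a single
`pipeline_config()`, deterministically for a fixed config and seed.

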