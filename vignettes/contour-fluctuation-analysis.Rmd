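---
title: "Polar contour fluctuation analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polar contour fluctuation analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contourdyn)
```

# The analysis model

`contourdyn` treats a time-lapse recording of one adherent cell as a
sequence of closed contours and asks three questions: what is the static
shape of the adhesion footprint, how does the shape fluctuate in space
and time, and how does the cell move?

## From images to contours

Adhesion footprints are darker than the surrounding background in
label-free interference-contrast imaging, so segmentation works on the
difference `background - frame`. The binarization chain is Otsu's
threshold, a morphological closing with a 3-px disk, hole filling, and
removal of objects below 20 µm² (`min_area_um2`). Neither the threshold
method nor a minimum footprint size is canonical for this kind of
read-out; both are explicit knobs of `segment_frame()`.

Two guards keep degenerate frames from becoming artifacts rather than
errors: a constant (or saturated) frame returns an empty mask with a
warning, and a frame whose brightest difference pixel is within 8 robust
standard deviations (MAD) of the background noise is declared
footprint-free — thresholding it would binarize the noise itself.

The default background is the per-pixel temporal median of the stack.
This assumes the cell *moves*; for a stationary cell the median at the
cell's core is the cell itself, and subtraction hollows the footprint
out. Rotation-only or pinned cells should therefore be segmented against
an explicit blank frame or background level (the `background` argument),
and the package's own tests do exactly that.

Geometry per frame: the area is the pixel count times `pixel_size²` and
the center of mass is the pixel centroid, both computed on the filled
largest component. The perimeter is the polygon length of the 0.5
isocontour of a Gaussian-smoothed (σ = 2 px) copy of the mask, traced by
marching squares. Tracing the raw pixel boundary instead would
overestimate perimeters by several percent (staircase bias), which
propagates quadratically into circularity; with the smoothed trace, a
disk of radius 100 px comes out within a few tenths of a percent in both
area and perimeter, and measured circularities stay below 1.02.

Coordinates are physical micrometres with y increasing upward; pixel
(row *i*, col *j*), 0-based, has its center at
`x = (j + 0.5)·px`, `y = (n_rows − i − 0.5)·px`. Multiple cells per
frame are handled by nearest-centroid linking from the previous frame's
center (largest component in the first frame, maximum jump 20 µm/frame
by default); frames with no linkable component are flagged as gaps,
never interpolated.

## Shape descriptors

Circularity is the isoperimetric ratio `4πA/L²`; with `A` and `L` as
inputs and a stated range of 0–1 this is the only dimensionless form,
and it is exactly 1 for a circle. Elongation is the minor-to-major axis
ratio from the principal axes of the region's second central area
moments, computed exactly on the contour polygon via Green's theorem.
A moment-based estimator was chosen over a bounding-box one because it
is rotation invariant by construction. Cohort tables report the sample
(n − 1) standard deviation.

## Amplitude maps and their autocorrelation

Each contour is sampled into a polar profile `r(θ)` about the per-frame
center by ray casting — 180 bins of 2° by default, θ = 0 at the
laboratory vertical, counterclockwise. For non-star-shaped contours a
ray can cross the boundary several times; the farthest crossing is used
and the event is reported. Crossings are assigned to polygon edges by a
half-open rule on the vertex polar angles, which keeps the count correct
when a ray passes exactly through a vertex.

The amplitude map removes the per-frame mean radius,
`ΔR(θ, t) = r(θ, t) − R̄(t)`, so every column has zero angular mean by
construction. The mean is per-frame, not global: a slowly spreading cell
would otherwise imprint its growth on every angle.

The autocorrelation is

```
G(Δθ, Δt) = Σ ΔR(θ, t) ΔR(θ + Δθ, t + Δt) / (N_pairs(Δt) · n_bins) / G₀
```

with periodic wrap in θ, every overlapping frame pair included, each
time lag divided by its own pair count (long lags are averaged, not
zero-padded, so they are unbiased), and the whole map divided by its
zero-lag value so `G(0,0) = 1`. The normalization is global rather than
per-lag: per-lag normalization would force every Δt slice to unit
maximum and erase the decay in time that distinguishes a rotating cell
(fast decay) from a persistently elongated one (slow decay). The map
satisfies `G(−Δθ, −Δt) = G(Δθ, Δt)` exactly and is stored on
Δθ ∈ (−180°, 180°], Δt symmetric about zero. Non-uniform timestamps are
linearly resampled onto the modal frame interval first.

One numerical guard: if the root-mean-square fluctuation is below 1e−4
of the mean radius (sub-nanometre for a 10-µm cell, far below optical
resolution), the map is declared flat and the correlation returned as
zeros with a warning. Without this, normalization would amplify the
polygon-discretization ripple of an ideal circle into a spurious
correlation pattern of unit height.

Peak localization scans a Δt slice for circular local maxima above
`min_height` (default 0.1), treating ±180° as one peak and reporting
plateau runs once. `ridge_slope()` follows the peak nearest Δθ = 0
outward through successive lags and fits a line through the unwrapped
positions; for a rigidly rotating shape the slope is the rotation rate.

## Motility and the deformation–direction distribution

The trajectory is the sequence of per-frame centers. Mean speed is the
average magnitude of displacements resampled onto a `dt = 30` min grid
(nearest frame), in µm/h — the standard sampling for adherent cells that
move a few µm/h; on straight-line motion the estimator is exact and
independent of `dt`.

The deformation–direction distribution asks whether shape and motion
are coupled. For every frame whose displacement over a centered 30-min
window exceeds a 0.5-µm noise floor (below that, direction is
undefined), the profile `ΔR(θ)` is rotated so 0° is the instantaneous
motion direction, and all (ΔR, relative angle) samples are accumulated
into a joint histogram (bins: 1 µm × 10°) normalized to total mass 1.
"Degree of deformation" is defined here as the radial fluctuation ΔR
itself, evaluated in the motility-aligned frame — this is an
interpretation, chosen because it carries the µm scale on which a
directional protrusion appears as an off-center sub-peak.

The motion-axis marginal is accumulated at the contour's angular
resolution (samples within one 2° polar bin of the motion axis) rather
than from the coarse 10° histogram columns: a raised-cosine protrusion
of 60° full width loses about 1.7 µm of its height within ±10°, so a
coarse marginal would systematically blur the sub-peak toward zero.

`symmetry_break_offset()` reports the most prominent local mode of the
marginal beyond one deformation bin from zero, provided it reaches 10%
of the central mode's mass and at least 55 contour lines contributed
(both configurable); ties are broken toward the motion direction
(positive ΔR), then toward the larger mass. A planted bump of height
`A` sits `A/12` above its angular mean (for the default 60° width), so
an 8-µm protrusion is detected at ≈ 7.3 µm — within one 1-µm bin of 8.

# The synthetic generator

No public recordings exist for this kind of experiment, so the package
ships a generative stand-in; **every law in it is a modelling choice,
not an inferred one**, and the point of the generator is controlled
ground truth, not realism.

* Contour: `r(θ, t) = R₀ (1 + Σ aₖ cos(kθ − φₖ(t)))` with
  `φₖ(t) = phase + k·ω·t`; Σ aₖ < 1 keeps the contour star-shaped.
  Defaults emulate footprints of a few hundred µm² (R₀ = 12 µm).
* Stochastic shape noise: a fresh random superposition of Fourier
  orders 2–8 each frame, scaled to a radial SD of `mode_noise_sd`.
  Smooth noise was chosen over white-per-vertex noise because real
  boundary fluctuations are correlated over tens of degrees; the
  consequence is that *angular* correlations at Δt = 0 are intrinsic to
  the noise model, and decorrelation statements are statements about
  Δt ≠ 0.
* Translocation: a persistent random walk — constant speed, direction a
  wrapped-normal increment process with variance `2·dt/P`, giving
  directional memory `exp(−t/P)`. It is the simplest process with one
  tunable persistence time.
* Protrusion: a single raised-cosine bump (default 60° full width)
  centered on the instantaneous heading; `protrusion_alignment` blends
  that center toward a uniformly random angle. Directed-migration
  scenarios use a long persistence time (≈ 50 h) because the phenomenon
  being emulated is hours-long unidirectional motion, and because the
  bump is placed along the *instantaneous* heading while the analysis
  measures direction over a 30-min window — with weak persistence the
  two disagree by several degrees and the narrow bump reads low.
* Adhesion kinetics: each of `n_cells_total` cells adheres with
  probability `plateau_fraction`; adhering cells draw an exponential
  attachment time with the configured half-time. Counts are cumulative,
  hence monotone within a realization.
* Rendering: interior pixels at `cell_level`, exterior at
  `background_level` (dark footprint requires `cell < background`),
  optional additive Gaussian noise, scanline polygon rasterization with
  the same pixel-center convention as segmentation.

The generator emits the *true* generative center as the per-frame
center of its contour series. This matters for protruded shapes: an
asymmetric 8-µm bump on a 12-µm cell pulls the area centroid 1–2 µm
toward itself, so profiles about the measured centroid read the bump
low. The segmentation path necessarily measures centroids; the
difference is a real, documented bias of centroid-referenced polar
profiles, not an implementation artifact.

What passing the synthetic tests does **not** show: robustness to
uneven illumination, interference fringes near the cell rim, cell
division and collisions, footprint topology changes (holes that are
real), or shape noise that is not a low-order Fourier field.

# Determinism and problem sizes

Every stochastic function takes a seed and restores the caller's RNG
state; identical inputs and seed give bit-identical output, and
`run_pipeline()` reruns byte-identically (outputs are stamped with a
configuration hash and the package version). The test and acceptance
workloads use 40–500 frames at 180 angular bins and 512 vertices per
contour, 10-cell cohorts, and 1000-replicate walk ensembles — sizes at
which every statistic above is stable to well inside its assertion
tolerance while the whole suite stays interactive on one CPU.

# Known limitations

* The temporal-median background fails for stationary cells (see
  above); supply a blank frame in that case.
* Polar profiles require the reference center to lie inside the
  contour; strongly concave shapes are handled by the
  farthest-crossing rule but their profile is no longer a function on
  the circle in any unique sense.
* The deformation marginal's sub-peak location estimates the protrusion
  *excess over the angular mean*, not the raw bump height; the `A/12`
  correction above is exact only for the raised-cosine shape.
* `mean_velocity()` with nearest-frame resampling assumes the frame
  interval divides `dt` reasonably; wildly irregular timestamps should
  be regularized first.
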