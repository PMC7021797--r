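---
title: "Methods: whole-cell 3D light-sheet dSTORM analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-cell 3D light-sheet dSTORM analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llsdstorm)
```

# Overview

`llsdstorm` implements the analysis chain for three-dimensional
single-molecule localization microscopy (dSTORM) performed on a stage-scanned
lattice light-sheet (LLS) microscope, applied to plasma-membrane receptors of
adherent cells. The chain is:

1. **Localization** — astigmatic elliptical-Gaussian fitting of blinking
   emitters, with z assigned from a bead-stack calibration
   (`calibrate_astigmatism()`, `localize_movie()`, `assign_z()`).
2. **Geometry** — correction for the sawtooth sample scan and rotation of the
   skewed acquisition volume into coverslip-aligned "biological" coordinates
   (`correct_scan_shift()`, `deskew_rotate()`).
3. **Density** — sliding-window localization densities over membrane regions
   with median ± MAD summaries (`sliding_window_density()`,
   `summarize_density()`).
4. **Tracking** — Crocker–Grier linking and per-dimension ensemble MSD
   diffusion fits (`link_localizations()`, `ensemble_msd()`,
   `fit_diffusion()`).
5. **FRAP** — normalization and single-exponential recovery fits
   (`normalize_trace()`, `fit_recovery()`).
6. **Precision** — empirical localization precision from blinking events
   (`estimate_precision()`).

A synthetic-data module generates ground-truth scenes, blinking movies,
Brownian trajectories and FRAP traces with the statistical structure the
analysis assumes, so every stage is testable without raw data.

Units are nanometres for lengths, seconds for times, and
localizations/µm² for densities; frame and stack indices are 0-based.

# Acquisition geometry and the deskew transform

The sample is stepped through the static light sheet by `scan_step` (default
40 nm) once per camera frame; `frames_per_stack` frames (default 1001) form
one sawtooth sweep covering `(frames_per_stack − 1) · scan_step` = 40 µm,
after which the stage snaps back and the next stack begins. Camera pixels are
103.8 nm at the sample, and the sheet thickness is ~1.4 µm, so localizations
further than 700 nm from the sheet plane are discarded
(`filter_localizations()`, `axial_halfwidth = 700`).

A camera frame sees a plane tilted by the deskew angle α relative to the
coverslip. With acquisition coordinates (x along camera columns, y along
camera rows, z the astigmatic depth from the sheet centre) and scan
coordinate `s = frame_in_stack · scan_step`, the biological coordinates are

$$x' = x,\qquad
  y' = s + y\cos\alpha - z\sin\alpha,\qquad
  z' = y\sin\alpha + z\cos\alpha .$$

The per-frame map is a rigid rotation about the x axis composed with a
translation along y′, so pairwise distances within a frame and densities per
true area are preserved; `invert_deskew()` is its exact algebraic inverse and
round-trips to 1e-9 relative tolerance.

Design choices worth making explicit:

* **The deskew angle is a configuration parameter, default 32.45°**, a
  conventional detection-axis tilt for this instrument class. Instruments
  differ; users must supply their own angle. Nothing in the package depends
  on the default being correct for a particular microscope.
* The scan translation is applied *together with* the rotation (s enters
  y′ directly). Whether the shift is subtracted before or after rotation is a
  convention; the composed transform here is fixed, documented, and
  invertible, which is what the downstream statistics require.
* With `anchor_coverslip = TRUE` the coverslip plane is set at the 1st
  percentile of z′ (robust to a small fraction of spurious low
  localizations); the offset is stored so inversion remains exact.
* Note a consequence of the geometry: the sheet plane satisfies
  `s = y' − z'·cot α`, so only points with `y' ≳ z'·cot α` are reachable by a
  scan starting at `s = 0`. Scenes (and real samples) must sit inside the
  scanned volume.

# Astigmatic localization

A cylindrical lens makes the PSF width anisotropic and z-dependent. The
calibration (`calibrate_astigmatism()`) fits beads plane-by-plane with the
elliptical-Gaussian model, pools widths across beads, fits quartic
polynomials σx(z), σy(z), re-centres z on the crossing point σx = σy, and
*rejects* calibrations whose width difference is not strictly monotone over
the valid range — without monotonicity, z assignment is ambiguous.

Spot fitting (`fit_spot()`) is maximum likelihood under Poisson noise for the
pixel-integrated model `µ = b + N·Gx·Gy` (box-constrained quasi-Newton on
the Poisson deviance, parameters scaled so photon counts and sub-pixel
positions converge together). The model is an *elliptical Gaussian*, a
deliberate simplification relative to interpolated experimental PSF models
used by dedicated SMLM engines; it is accurate for the mildly astigmatic
regime simulated here and keeps the package self-contained. Non-converged
fits are flagged (`converged` column), never silently dropped.

z assignment (`assign_z()`) minimizes the square-root width metric
$(\sqrt{\sigma_x}-\sqrt{\sigma_{x,\mathrm{cal}}(z)})^2 +
 (\sqrt{\sigma_y}-\sqrt{\sigma_{y,\mathrm{cal}}(z)})^2$
— standard astigmatism practice, since the square root tempers the weight of
the large defocused widths — by a 1 nm grid search with parabolic
refinement; ties break toward smaller |z|; minima on the range boundary, or
width pairs whose residual mismatch exceeds 2 √nm, are flagged invalid.
Detection (`detect_spots()`) is a difference-of-Gaussians band-pass with
8-connected maxima above a robust (MAD) noise threshold; two emitters closer
than the minimum separation merge into one candidate — multi-emitter fitting
is out of scope.

Default photon threshold: `min_photons = 500`. It is configurable and logged;
the right value depends on dye and buffer.

# Localization precision from blinking events

A fluorophore's single on-period yields localizations in consecutive frames;
their scatter measures precision without ground truth. Localizations within
`group_radius` (default 100 nm, lateral) in frames at most `max_gap + 1`
apart are grouped into events; the per-dimension estimate is the pooled
within-event standard deviation over events with ≥ 2 members. Grouping is
used *only* here — localization tables are otherwise left uncorrected for
overcounting, matching the upstream convention of not merging repeat
emissions. Grouping uses lateral distance only, because axial precision is
several-fold worse and would dominate a 3D radius.

# Sliding-window densities

Regions are simple polygons in a named projection plane with slab bounds
(`region_mask()`); points in the (half-open) slab are orthogonally projected
(`project_to_plane()`). Windows of 2 µm × 2 µm are centred on a 0.2 µm grid;
a window is kept only when fully inside the polygon (corner test; exact for
rectangles and convex masks) — edge windows are dropped, not rescaled, which
avoids inflated variance at region borders at the cost of discarding a rim of
data. Window membership is half-open per axis so adjacent windows never
double-count a point. When `window_size/step` is an integer the counts are
computed exactly via step-sized bins and a summed-area table; otherwise by
direct counting.

Summaries report the median, the *raw* median absolute deviation (no 1.4826
normal-consistency factor — the "median ± MAD" convention), quartiles, and
1.5×IQR whiskers drawn to the furthest datum inside the fence.

Two documented biases: densities are per *projected* area, so membrane
inclination against the projection plane inflates apical densities (no
curvature correction is applied); and a cell–cell interface consists of two
apposed membranes a few tens of nanometres apart, which no projection can
separate — interface windows therefore count both membranes, and analyses
that need a per-membrane figure halve the interface density (the worked
end-to-end example and the acceptance script do exactly that, explicitly).

# Tracking and diffusion

`link_localizations()` implements the Crocker–Grier assignment: frame to
frame, the linking of open track ends to new localizations that minimizes
total squared displacement among candidates within `max_disp` (default
500 nm), a non-link costing `max_disp²`; unmatched points open new tracks and
track ends survive `memory` frames (default 1). The optimal assignment is
solved exactly by exhaustive enumeration inside connected candidate
subnetworks; subnetworks larger than `max_subnet` (default 10, rare at
trackable densities) fall back to a greedy assignment with a warning.

Per-dimension time-averaged MSDs use all overlapping pairs (standard
practice; it correlates successive lag points, which is why the fit is
restricted to the first few lags). The ensemble MSD over tracks of ≥ 20
localizations is the pair-count-weighted mean per lag. `fit_diffusion()`
performs unweighted ordinary least squares of

$$\langle \Delta r^2\rangle(\tau) = o + 2D\tau$$

per dimension on the first 5 lag points (both defaults configurable). The
offset `o` reflects the squared static localization error (`o ≈ 2σ²`); on
noisy data it may fit negative and is reported as-is with a warning —
clamping would bias D. Anomalous-diffusion models and motion-blur corrections
are out of scope; the short-lag linear fit is the deliberate regime.

# FRAP

Traces are normalized to a prebleach mean of exactly 1 after background
subtraction, making fits invariant to gain. Recovery is fit on post-bleach
points with the single-exponential model

$$I(t) = I_0 + \mathrm{MF}\,(1 - I_0)\,(1 - e^{-(t - t_\mathrm{bleach})/\tau}),$$

an artifact choice: it is the simplest model with a time constant and a
mobile fraction, which is all the downstream claims use. A
diffusion-equation (Soumpasis) model is deliberately not implemented. Flat
post-bleach traces are resolved analytically (MF = 1 if fully recovered,
MF = 0 otherwise) with `tau = NA`, since no time constant is identifiable.
The mobile fraction is clipped into [0, 1] with a warning if the optimum
falls outside. Defaults follow the acquisition protocol: 1.5 s frames, 120 s
total, bleach after 3 images.

# The synthetic-data module

The generator defines the study conditions under which the pipeline is
validated.

* **Scene**: two spherical-cap cells (radius 4 µm, height 6 µm) on a
  coverslip, each truncated by a vertical contact plane; the flattened
  contact discs, 20 nm apart, form the interface. This is the minimal
  geometry exhibiting basal / apical / interface regions with a finite-area
  interface patch; real cell contacts are flattened membrane appositions, so
  a flat contact disc is the appropriate idealization (a tangent-sphere
  contact would have vanishing area). The scene is smaller than a typical
  293T cell to keep simulated volumes tractable; region statistics scale
  with area, not cell size. Emitter counts per region are
  Poisson(density × area) with positions uniform on the surface.
* **Blinking**: memoryless activation, geometric on-times, then bleaching —
  or, with `recurrence = 1`, indefinite cycling that models the
  photoswitching quasi-equilibrium of dSTORM: per-frame occupancy is then
  stationary at ≈ activation_rate × mean_on_time, which matters under
  sawtooth scanning because different sample depths are visible at different
  times within a stack; a depleting fluorophore pool would otherwise couple
  region yield to scan phase. Kinetic constants are free parameters (real
  constants for these dyes and buffers are not established numbers).
* **Image formation**: pixel-integrated elliptical Gaussians with widths from
  the astigmatism calibration, Poisson shot noise and background, linear
  camera gain/offset with optional Gaussian read noise. sCMOS per-pixel noise
  maps, dipole emission and drift are *not* modelled — passing tests
  demonstrate correctness of the estimators under the stated model, not
  robustness to those instrument effects.
* **Trajectories**: per-dimension Gaussian increments with variance 2 D dt
  plus i.i.d. localization noise; anisotropic D supported.
* **FRAP**: exact evaluation of the recovery model plus Gaussian noise,
  optionally scaled back to raw camera units.

All generators are reproducible given a seed, restoring the caller's RNG
state afterwards.

# Numerical choices and degenerate inputs

* z grid for assignment: 1 nm, parabolic refinement, ties toward smaller |z|.
* Spot fits: L-BFGS-B with per-parameter scaling; widths bounded in
  [0.3, ROI] px; all-zero or NA ROIs are errors, not silent skips.
* Quartic polynomials for the calibration curves; 10% of the scanned range is
  trimmed from each end where defocus fits degrade.
* Window counting uses exact integer bin alignment when
  `window_size/step` is integral (it is, at the defaults 2000/200).
* Zero-thickness slabs are permitted and select nothing (half-open bounds).
* Empty movies, header-only tables and all-dark blinking runs all return
  empty-but-well-formed objects.

# Problem sizes

The test suite and the acceptance script run at desk scale, chosen so every
stochastic check has comfortable statistical margin: 200–250 trajectories of
50 frames for diffusion recovery; ~60,000 localizations for the two-cell
density scene (two stacks of 1001 frames); 20 replicates per intensity for
the Poisson density medians; ~400 Monte-Carlo fits per photon level for the
precision-scaling law; thousands of blinking events for precision pooling.
The full-scale acquisition plan (1001 × 573 frames) is exercised
arithmetically and through the scan-plan bookkeeping, not by rendering.

# Known limitations

* The elliptical-Gaussian PSF is a model simplification; experimental PSFs
  with aberrations will bias z more than the simulated tests indicate.
* Precision estimates in the rotated frame apply the estimator to rotated
  coordinates directly; because event noise is anisotropic and the rotation
  mixes axes, rotated-frame figures are not a simple rotation of
  acquisition-frame figures.
* No drift correction, no chromatic registration, no multi-emitter fitting,
  no cluster statistics (densities only), no GPU path.
* Region masks are user-supplied polygons (or simulated truth); automatic
  membrane segmentation is out of scope.
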