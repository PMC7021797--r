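# llsdstorm

Analysis of whole-cell 3D single-molecule localization microscopy (dSTORM)
acquired on a stage-scanned lattice light-sheet microscope, for quantifying
the expression, distribution and mobility of plasma-membrane receptors on
intact cells — including the membrane regions a TIRF microscope never sees
(apical surface, cell–cell interfaces).

It is aimed at microscopists and image analysts who have (or simulate)
blinking-emitter movies or localization tables from such an instrument and
want, in one package: astigmatic 3D localization, transformation of the
skewed scanned volume into coverslip coordinates, membrane-region density
statistics, single-particle-tracking diffusion analysis, FRAP recovery fits,
and empirical localization-precision estimates — plus a synthetic-data
generator so every stage can be validated without raw data.

## The models at the core

**Deskew/rotation.** The sample is stepped 40 nm per frame through the sheet
in a sawtooth (1001 frames per stack). With scan coordinate
`s = frame_in_stack · scan_step` and deskew angle α, acquisition coordinates
map to biological (coverslip-aligned) coordinates by

    x' = x
    y' = s + y·cos α − z·sin α
    z' = y·sin α + z·cos α

a rigid per-frame transform: distances and densities are preserved, and the
inverse is exact.

**Astigmatic z.** Bead stacks calibrate the defocus curves σx(z), σy(z)
(quartic polynomials, monotone width difference required); spots are fit by
Poisson maximum likelihood with a pixel-integrated elliptical Gaussian and z
is assigned by minimizing `(√σx−√σx_cal(z))² + (√σy−√σy_cal(z))²`.

**Density.** Localizations projected onto a region mask are counted in
2 µm × 2 µm windows sliding on a 0.2 µm grid; summaries report the median ±
raw MAD (and quartiles/1.5×IQR whiskers).

**Diffusion.** Localizations are linked with the Crocker–Grier assignment;
the ensemble mean square displacement of all tracks of ≥ 20 frames is fit per
dimension on its first five lag points with

    ⟨Δr²⟩(τ) = o + 2·D·τ

where `o` reflects the squared localization precision.

**FRAP.** Traces normalized to a unit prebleach mean are fit with
`I(t) = I₀ + MF·(1−I₀)·(1−exp(−t/τ))` for the time constant τ and mobile
fraction MF.

## Worked example

Simulate 250 receptors diffusing anisotropically in a membrane (x/y free,
z constrained), imaged at 20 ms/frame with realistic localization noise,
then run the full tracking pipeline:

```r
library(llsdstorm)

sim <- simulate_trajectories(250, D = c(0.058, 0.059, 0.023), dt = 0.02,
                             n_frames = 50, noise_sigma = c(20, 20, 70),
                             seed = 1)
tracks <- link_localizations(sim$observed, max_disp = 500, memory = 1,
                             dt = 0.02)
tracks
#> Trajectory set: 250 tracks, lengths 50..50 (dt = 0.02 s)

fit <- fit_diffusion(ensemble_msd(tracks, min_track_len = 20),
                     n_fit_points = 5)
fit
#> Free-diffusion fit (first 5 lags, MSD = o + 2 D tau):
#>   D_x = 0.0572 +/- 0.0002 um^2/s, o_x = 907 +/- 23 nm^2
#>   D_y = 0.0606 +/- 0.0001 um^2/s, o_y = 712 +/- 9 nm^2
#>   D_z = 0.0217 +/- 0.0004 um^2/s, o_z = 9718 +/- 56 nm^2
```

The fitted diffusion constants recover the simulation inputs
(0.058/0.059/0.023 µm²/s) within a few percent, and the offsets match the
squared localization noise (`o ≈ 2σ²`: 800 nm² laterally, 9800 nm² axially).
A FRAP trace behaves the same way:

```r
tr <- simulate_frap(tau = 15, mobile_fraction = 0.8, noise_sd = 0.01,
                    seed = 1)
fit_recovery(normalize_trace(tr$intensity, 0, 3, times = tr$t))
#> FRAP recovery fit (single exponential):
#>   tau = 15.15 s, mobile fraction = 0.804, I0 = 0.308 (RMS 0.0090)
```

See `vignettes/llsdstorm-methods.Rmd` for the full account of the models,
conventions and design choices, and `inst/cli/llsdstorm.R` for a thin
command-line front end whose stages chain via CSV/TIFF/YAML files.

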