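---
title: "Models and methods behind smlmpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smlmpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

smlmpipe implements the image-analysis chain used in correlative in-resin
single-molecule localization microscopy (SMLM) and transmission electron
microscopy (TEM): a forward simulator of photo-switching fluorophore
movies, maximum-likelihood localization, data-driven accuracy estimation,
density-based structural-resolution estimation, density-coded rendering,
and control-point registration between the fluorescence and EM coordinate
systems. This vignette explains the underlying models, the defaults, and
the design decisions — in the spirit of the long-form methods vignettes of
packages like DESeq2 or vegan.

## The forward model: blinking fluorophores on a structure

A specimen is a set of fluorophore positions decorating a parametrized
structure (`generate_structure()`): parallel membrane profiles at a fixed
spacing, single membranes, vesicle-like rings, nuclear blob clusters, or a
uniform field. Emitter counts are Poisson around density x measure, so
repeated simulations carry realistic counting noise.

Photo-switching (`simulate_switching()`) follows the standard model for
fluorescent proteins under strong excitation: molecules sit in a
long-lived dark state (seconds to minutes; default recovery rate 0.02/s),
stochastically recover to an emissive state for an exponential on-time
(mean 60 ms), emit a uniform draw of 100-1000 detected photons per burst,
and then either bleach irreversibly (probability `bleach_prob`) or return
to the dark state. Bursts are binned into camera integration windows
(50 ms exposure at 17 frames per second by default; photons emitted in the
8.8 ms dead time between exposures are lost), split across frames in
proportion to the in-frame on-time. Because the mean on-time (~60 ms)
exceeds one exposure, a large fraction of bursts spans two consecutive
frames — the raw material for the adjacent-frame accuracy estimator below.

The camera (`camera_model()`) is an EMCCD reduced to the variance
structure that matters downstream: expected photons are Poisson-drawn,
multiplied by the EM gain, and Gaussian read noise plus a baseline offset
are added. The full EM-register gain cascade is deliberately omitted; the
estimators only see the mean/variance behavior. The pixel size defaults to
80 nm (a typical EMCCD pixel behind a 100x objective; the imaging
literature this emulates does not state one) and the PSF to a Gaussian
with sigma = 0.25 lambda / NA (lambda = 510 nm, NA = 1.4, i.e. ~91 nm), the
standard Gaussian approximation of the Airy core.

### The non-switching background population

Densely labeled specimens contain a population of molecules that never
enters the dark state; it raises the background early in a measurement and
photo-bleaches away over its course, which is why localization accuracy
*improves* during acquisition. Two representations are provided:

* sparse explicit emitters (`nonswitching_fraction` in
  `switching_params()`), simulated per molecule with exponential bleaching
  — appropriate when non-switching molecules are isolated;
* a mean-field glow (`nonswitching_background_image()` plus
  `render_movie(background_image =, background_decay_rate =)`) for the
  dense regime. At the densities where this population matters there are
  many molecules per diffraction-limited area, so their summed image is a
  smooth, structured background, not a set of fittable spots. The glow
  decays exponentially in expectation; per-frame Poisson noise is still
  applied in full, only the discreteness of individual bleaching steps is
  averaged out.

The distinction is not cosmetic: at ~1 molecule per PSF footprint the
background is maximally lumpy and each lump is PSF-shaped, so a localizer
will (correctly!) fit the lump whenever shot noise triggers a detection
there. The accuracy-trend study therefore uses the dense mean-field glow,
with the mean level (~60 photons/pixel/frame at the start, decaying with
rate 0.04/s) chosen so that the early-phase Cramér-Rao bound sits near the
~17 nm accuracy regime reported for dense nuclear specimens.

## Localization

`localize_movie()` chains four steps.

**Background subtraction** (`subtract_background()`): per pixel, the
temporal median over a sliding window of 21 frames (half-window 10) is
subtracted. The median of 21 values ignores bursts of up to ~half the
window, so blinking emitters survive while stationary background — camera
offset, cellular autofluorescence, the non-switching glow — is removed.
The residual stack keeps its sign; detection clamps at zero.

**Detection** (`detect_candidates()`): local maxima of the clamped
residual above `threshold x sigma_noise`, with a minimum peak separation
of 2 px; `sigma_noise` is robust (1.4826 x MAD). Because shot noise varies
across a structured background, `localize_movie()` estimates a per-pixel
noise map from the residual time series (`residual_noise_map()`) in
temporal blocks of 150 frames, so the threshold adapts both to spatial
background structure and to slow bleaching. Default threshold: 4 sigma.

**Fitting** (`fit_spot_mle()`): each candidate's 7x7 px ROI, converted
back to photons (`(counts - offset) / gain`), is fit by maximizing the
Poisson likelihood of an integrated-Gaussian spot model
`mu_i = N G_i(x0, y0, sigma) + b` over all five parameters, with analytic
gradients under L-BFGS-B. The likelihood is evaluated on the raw
(nonnegative) ROI with `b` free rather than on the signed residual,
because the Poisson model requires nonnegative counts. `sigma` is bounded
to [0.5, 2] x the nominal PSF sigma — section-induced aberrations of
unknown magnitude can broaden spots — and fits that pin `sigma` at either
bound or run the position to the ROI edge are rejected as degenerate
boundary optima (empirically these are noise clusters, and rejecting them
removes essentially all false localizations). A cheap pre-fit gate skips
ROIs whose clamped residual mass cannot plausibly reach a third of the
photon filter; this only saves time, it cannot create detections.

**Filtering and merging**: fits below 100 photons (the lower end of the
detected single-molecule photon range) are dropped, and detections of the
same burst in consecutive frames within 50 nm are merged into one record
at the photon-weighted mean position (`n_merged` counts the chain length;
photons are summed). Merging is on by default because ~60 ms on-times at
50 ms exposures make two-frame bursts common. The pre-merge records are
retained in the table's `unmerged` attribute, since the accuracy estimator
below consumes exactly the pairs that merging collapses. Fit quality on
this model is verified against the Cramér-Rao bound: across 200-1000
photons the empirical position scatter of repeated fits stays within 15%
of the bound (`crlb_sigma_px()`).

## Accuracy from the data: adjacent-frame nearest neighbors

A burst spanning two frames is localized twice; the distance between the
two localizations is governed purely by the localization error,
independent of any photon-count model. If each localization has isotropic
per-axis error sd sigma, the pair distance is Rayleigh with scale
sigma * sqrt(2):

    p(d) = d / (2 sigma^2) * exp(-d^2 / (4 sigma^2)).

`estimate_accuracy_nena()` collects, for every localization in frame t,
the nearest neighbor in frame t+1 within a 200 nm search radius, and fits
the binned distances (2 nm bins) by multinomial maximum likelihood to a
mixture of this same-molecule model (truncated at the radius) and a linear
term `2d/R^2` for false pairs uniform in area. The reported accuracy is
the per-axis sigma — the convention that makes the structural-resolution
arithmetic below consistent (FWHM = 2.35 sigma; quoting ~17 nm accuracy
alongside a 40-50 nm structural resolution only works per-axis).
A 95% confidence halfwidth comes from the observed information.
`accuracy_trend()` splits the acquisition into equal-frame epochs and
estimates per epoch, tracing the accuracy improvement as the non-switching
background bleaches. Epochs with fewer than 50 pairs are flagged invalid
rather than failing the trend.

## Density, Nyquist limit and structural resolution

Localization accuracy is only half of image quality; the other half is how
densely the structure is sampled. For every localization,
`estimate_resolution()` computes the mean distance to its K = 20 nearest
neighbors (exact kd-tree search). Because the neighbors of a point in a
random pattern cannot all sit at one radius, the mean K-NN distance of a
uniform Poisson process of intensity rho is not 1/sqrt(rho) but
`c_K / sqrt(rho)` with the circular-symmetry normalization

    c_K = (1 / (K sqrt(pi))) * sum_{k=1..K} Gamma(k + 1/2) / Gamma(k),

(c_1 = 1/2, c_20 ~ 1.7134; verified by Monte Carlo to well under 1%).
Local density is then `rho = (c_K / mean_dist)^2`, the Nyquist-limited
resolution `R_N = 2 / sqrt(rho)` (twice the mean sampling interval), and
the structural resolution combines localization FWHM and sampling in
quadrature:

    R = sqrt((2.35 sigma)^2 + R_N^2).

At sigma = 17 nm and rho = 22,000/um^2 (R_N = 13.5 nm) this gives ~42 nm —
the arithmetic that connects per-molecule accuracy, labeling density and
the 40-50 nm structural resolution regime; 22,000/um^2 is >1,000 molecules
per 250 nm-diameter diffraction-limited area, and 40,000/um^2 is ~2,000.

Two numerical caveats are built in. First, points whose K-th neighbor is
farther than the field border are flagged and excluded from summaries
(edge correction). Second, the per-point density inherits a small positive
Jensen bias (~6% at K = 20) because the reciprocal square is convex in the
distance; the field-level estimate `field_density()` — square of c_K over
the *mean* distance — is unbiased and is what the summaries report
alongside the per-point mean. Exact duplicate coordinates would give
infinite density; they are excluded with a warning rather than jittered.

## Rendering

`render_sr_image()` draws each localization as a unit-mass integrated
Gaussian with sd `max(sigma_loc, R_N_i / 2.35, floor)`: where sampling is
dense the kernel is the localization accuracy, where it is sparse the
kernel widens to the local Nyquist equivalent, so the image never suggests
more resolution than the data carry. A parallel raster accumulates
density-weighted mass, giving each pixel a mass-weighted mean local
density that is mapped through a colormap with a dual legend (density and
the corresponding Nyquist resolution). Mass is conserved (sum of raster =
record count, up to 4-sigma kernel truncation and field clipping), and as
the kernel floor grows the rendering converges exactly to the
diffraction-limited reference `render_widefield_reference()` (a 250 nm
FWHM convolution of the same positions).

## Registration and line profiles

Matched feature positions in the SMLM (nm) and EM (px) images determine
the mapping between the two coordinate systems
(`estimate_transform()`): a similarity transform — the "linear conformal"
map of rotation, uniform scale and translation, solved in closed form by
scaled orthogonal Procrustes (SVD) — suffices when the section does not
shrink anisotropically during EM acquisition; a full affine fit (normal
equations) absorbs shrinkage and shear. The tool reports residuals for
whichever is requested and never auto-selects, since "significant
shrinkage" is a judgment call; the affine residual can never exceed the
similarity residual on the same points (nested least squares). Reflections
are excluded by default and available by flag. `make_overlay()` resamples
the rendering into the EM frame by inverse mapping with bilinear
interpolation and alpha-composites it; `line_profile()` extracts
width-averaged intensity profiles, with TEM profiles conventionally
inverted (max minus value) so electron-dense membranes compare directly
with bright fluorescence ridges.

`count_profile_peaks()` decides how many structures a profile resolves: a
local maximum counts as separate only if the saddle toward the nearest
higher peak dips by at least 35%. The threshold is slightly stricter than
the Rayleigh criterion (the Airy dip at the Rayleigh separation is ~26%).
This matters for the canonical comparison: a 300 nm membrane pair under an
ideal 250 nm-FWHM Gaussian still retains a ~27% dip mathematically, yet no
observer — and no aberrated real wide-field system — calls that resolved;
with the 35% rule the wide-field profile is single-peaked while
super-resolution and inverted-TEM profiles of the same pair are cleanly
two-peaked.

## The pipeline and reproducibility

`run_pipeline()` executes simulate, localize, quality, resolution, render
and register from a YAML/JSON config (see
`system.file("extdata", "demo_config.yaml", package = "smlmpipe")`),
validates the config before running, retains partial outputs when a stage
fails, and writes a manifest with parameters, seeds and md5 hashes of
every artifact. All randomness flows from explicit seeds (no hidden global
state); identical config and seed reproduce identical hashes bit for bit.

## Study sizes, what the simulations show — and what they do not

The accuracy-trend study simulates a 96 x 96 px field (7.68 um side) for
1,200 frames at 17 fps (~71 s): 800 switching emitters (recovery 0.05/s,
bleach probability 0.2 per burst) over a dense non-switching glow (~60
photons/px/frame initially, bleaching at 0.04/s). These sizes keep a full
simulate-localize-trend cycle within a few minutes on one core while
leaving hundreds of NeNA pairs per epoch; they are scaled-down analogs of
a 15,000-frame acquisition, not a replica. Detection benchmarks use ~300
emitters over 200 frames at low background.

The generator emulates blinking statistics, photon budgets, EMCCD noise,
structured decaying background, and EM-like images under known transforms.
It does not emulate stage drift, sample tilt, 3D defocus, spectral
crosstalk, spatially varying excitation, or non-Poisson EM-register noise
— so passing tests demonstrate the estimators' correctness under the
stated model, not robustness to every artifact of real acquisitions.
Degenerate inputs are handled explicitly: flat ROIs flag rather than
throw, duplicate coordinates are excluded from density with a warning,
epochs with too few pairs are marked invalid, and singular or collinear
control-point configurations raise structured errors.
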