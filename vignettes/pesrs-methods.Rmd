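---
title: "Models and methods behind pesrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pesrs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pesrs implements the analysis chain used for single-molecule detection in
plasmon-enhanced stimulated Raman scattering (PESRS) microscopy: a raw
hyperspectral cube is denoised, its broad non-Raman background is removed
pixel by pixel, the residual Raman signal is unmixed into isotopologue
contributions, and single-pixel events are selected, classified, and
characterized by their line shapes and temporal behavior. Because no raw
instrument data are deposited for this kind of experiment, the package
carries a fully ground-truthed synthetic scene generator, and every stage
is validated by recovery against that truth. This vignette explains the
models, the defaults, and the choices that were genuinely open.

## The signal model and the scene generator

A PESRS acquisition is a cube of 200 x 200 pixels x 80 Raman channels
(40,000 single-pixel spectra) scanned at 150 nm pitch with 10 us dwell.
The standard spectral axis spans 550-850 cm^-1 at 13.7 cm^-1 instrument
resolution; a high-resolution mode used for isotopologue discrimination
has 120 points over 565-850 cm^-1 at about 7 cm^-1. Both are constructor
presets (`axis_standard()`, `axis_highres()`).

The generator (`generate_scene()`, `render_cube()`) emulates a dried
colloidal gold substrate:

* **Aggregates** are placed uniformly at random (no wrap-around, kept a
  margin away from the image edge so the point spread function never
  truncates signal mass). Each carries a background amplitude and an
  enhancement scale.
* **Hot spots** sit inside aggregates; their enhancement `g` is
  log-normal around the aggregate scale. Heavy-tailed enhancement is the
  standard phenomenological model for plasmonic hot spots; no
  electromagnetic simulation is attempted.
* **Molecules** occupy hot spots with Poisson(mu) counts; each is
  14N-adenine with probability `f14`, else the 15N isotopologue, and has
  a log-normal per-molecule weight `eta`.
* **Bands** are Fano profiles with unit peak height in the Lorentzian
  limit. Defaults: 733 cm^-1 (14NA), 726 cm^-1 (15NA ensemble; a
  single-pixel variant at 724 cm^-1 is available), width 10 cm^-1,
  asymmetry q = 1000 (effectively Lorentzian; dispersive shapes are
  produced by lowering |q|). Signal is strictly linear in pump and in
  Stokes power, normalized to the 0.15 mW / 0.15 mW operating point.
* **Background** is the dominant feature of raw PESRS spectra: per
  pixel, an amplitude proportional to local aggregate density times a
  gentle second-order polynomial in the spectral coordinate with a small
  random per-pixel tilt. The experiment characterizes this background
  only qualitatively (broad, largely independent of Raman shift), so the
  functional form is a package choice; the peak-to-background ratio is a
  free parameter, with defaults (amplitude 10 vs typical single-molecule
  peak 1) chosen so the marker band is a small feature on a large
  pedestal, as in measured spectra.
* **PSF**: the molecular signal is blurred by a unit-mass Gaussian of
  400 nm FWHM (diffraction-limited near-IR focus at NA ~ 1.2), i.e.
  ~1.1 px SD at 150 nm pitch. Unit mass means the blur flattens a
  point emitter's peak about 8-fold, which sets the amplitude
  calibration below.
* **Noise and amplitude calibration**: noise is additive i.i.d.
  Gaussian (detector-limited), default sigma 0.12, and the default
  per-molecule amplitude (`signal_scale = 8`) is chosen so that a
  typical single molecule, after PSF flattening, has a raw single-pixel
  peak SNR near 8 — the regime where denoising brings single-pixel SNR
  to the reported ~33 scale, a ~3-4x gain. A signal-dependent noise
  term is deliberately not included: the experiment does not
  characterize its noise floor, and a misspecified shot-noise model
  would be worse than an honest Gaussian one.

What the generator does *not* emulate: correlated (1/f or line) noise,
substrate drift, spectral response ripple, saturation, and the
wavelength dependence of plasmonic enhancement across the window. Tests
that pass against this generator therefore demonstrate algorithmic
correctness under the stated signal model, not robustness to every
instrument artifact.

Time-lapse stacks (`render_timelapse()`) give each molecule a state
trajectory: stable, two-state telegraph blinking (initialized from the
stationary distribution so occupancy statistics are frame-invariant), or
one-step irreversible bleaching; the background field is static across
frames and noise is redrawn per frame.

## Baseline removal: airPLS over a Whittaker smoother

The broad non-Raman background is removed by adaptive iteratively
reweighted penalized least squares. The inner smoother minimizes

    sum_i w_i (y_i - z_i)^2 + lambda sum_j (z_{j-1} - 2 z_j + z_{j+1})^2,

a pentadiagonal SPD system solved by banded Cholesky in O(n) per
spectrum (the per-pixel loop over a full cube is compiled). The outer
loop starts from uniform weights; channels where the residual d = y - z
is non-negative (peaks) get weight zero, channels below the fit get
weight exp(t |d_i| / D) with D the summed negative residual, and the two
boundary channels are pinned to the maximum weight so the baseline stays
anchored. Iteration stops when D < tol |y|_1 (tol = 0.001) or after 30
iterations. These internals follow the published algorithm that the
field uses, since the experiment names the method without equations; the
order-2 penalty is fixed as in its standard form, and the endpoint
weighting follows the algorithm's reference implementations.

Two behaviors of this estimator are worth knowing. First, it converges
toward the *lower envelope* of the noise, so baseline-corrected spectra
carry a uniform positive offset on the order of one to two noise SDs;
this offset is spectrally flat (the tests check that no band-window
structure is invented) and cancels in peak positions and ratios, but it
means corrected intensities are not unbiased estimates of zero off
resonance. Second, there is a lambda trade-off for band areas: a
flexible smoother climbs into the band wings and clips 20-35% of the
area at lambda near 1e2, while a very stiff one (1e4 and beyond on an
80-channel window) sags below curved backgrounds between its anchor
regions and inflates small areas. Band areas are recovered within 10%
over the central decade around the default lambda = 1e3, which is where
the tests pin the property.

The default lambda = 1000 was chosen once for the 80-channel window so
the smoother's effective bandwidth is several band widths — wide enough
not to absorb a 10 cm^-1 peak, narrow enough to track the background
curvature — and validated by the recovery property (band area recovered
within 10% for lambda anywhere in [1e2, 1e4]). It is exposed in the
configuration. Degenerate inputs: exact reconstruction y = z + corrected
holds for every spectrum by construction; an all-flat spectrum converges
in one iteration; per-pixel non-convergence over a cube is flagged, not
fatal.

## Denoising: block-matching collaborative filtering

The denoiser follows the grouping + collaborative filtering paradigm:
for each reference 3D patch (4 x 4 pixels x 16 channels), the most
similar patches within a 12-pixel search window are stacked into a 4D
group; an orthonormal DCT is applied separably along all four
dimensions; coefficients below 2.7 sigma are zeroed (first pass) or
Wiener-shrunk using the first pass as pilot (second pass); patches are
aggregated back with weights inversely proportional to the retained
coefficient count. A faithful port of the full reference implementation
of volumetric block-matching is out of scope; this implementation
captures the mechanism the analysis relies on — exploiting nonlocal
spatial and local spectral correlation — with every parameter exposed,
and is validated by recovery properties (SNR gain, band-centroid
preservation) rather than by equivalence to any particular binary.

Numerical choices worth noting: matching runs on a 3x3x3 box-prefiltered
cube so grouping is not noise-driven; the spectral dimension is never
split across groups; patch visitation is raster order and distance ties
break by raster order, making the output bit-deterministic; the group DC
coefficient always passes through, which gives exact DC preservation
(adding a constant to the input adds exactly that constant to the
output). Noise SD is estimated from the MAD of spectral second
differences (scaled by 1/(0.6745 sqrt(6))), which is blind to smooth
signal and to offsets.

## Unmixing: MCR-ALS with non-negativity

The corrected cube, flattened to pixels x channels, is factorized as
D ~ C S with C >= 0 and S >= 0 — the two constraints the experimental
analysis names — by alternating least squares. Both half-steps are
*exact* NNLS solves: for k <= 8 components the global optimum is found
by support-set enumeration (the optimum restricted to its support is the
unconstrained solution there), which vectorizes over all 40,000 pixels;
this guarantees the residual norm is non-increasing, which clipped
unconstrained updates would not. Each iteration ends with S rows
renormalized to unit maximum and the scale absorbed into C, fixing the
usual bilinear scale ambiguity. Convergence is declared on the relative
change of the lack of fit, lof = 100 sqrt(sum (D - CS)^2 / sum D^2),
below 1e-4, the convention of the standard MCR-ALS tooling, since no
tolerance is stated by the experiment. Initialization follows the
experimental protocol: normalized spectra from isotopically pure
reference samples (top-decile-intensity pixels averaged, clipped,
unit-max normalized). No closure or unimodality constraints are applied
— only non-negativity is warranted. Rank-deficient initializations get a
ridge-stabilized update and a warning.

One pitfall deserves its own paragraph. A dataset in which nearly every
pixel holds the *same* blend of the two isotopologues (the
high-concentration control regime) is rank-deficient for a free
bilinear fit: many (C, S) pairs explain it equally well, and iterating
ALS slowly rotates the spectra away from the references while the lack
of fit creeps down by fitting residual structure. We measured exactly
this — spectra correlation to the references falling from 0.99 to 0.67
over eight iterations while lof improved from 18.4% to 16.1%. The
pipeline therefore factorizes the mixture cube *jointly* with the
processed pure-reference cubes (standard MCR multiset augmentation):
the pure pixels anchor each component using nothing beyond the
non-negativity constraint, and the mixture rows of C are reported.
This is the pipeline default whenever reference cubes are supplied
(`mcr$augment_refs`); `mcr_als()` itself is the plain alternating
algorithm. Isotopologue unmixing also requires the high-resolution
acquisition mode: at 13.7 cm^-1 standard resolution the 726/733 cm^-1
bands are a single channel apart and no constraint set can separate
them, which is exactly why the instrument adds chirp for this
measurement.

## Event statistics and the bianalyte model

A pixel is an event iff its corrected spectrum peaks inside the 715-745
cm^-1 marker window and that maximum exceeds tau = 0.03. The
experimental threshold is quoted in unstated instrument units, so the
package applies it on a normalized scale (cube divided by its global
maximum), keeping the default transferable; absolute thresholding
remains available. The relative 14NA contribution p = C14/(C14+C15) is
classified with edges that operationalize the qualitative "ratio ~ 0 or
~ 1" reading: p <= 0.1 -> SM15, p >= 0.9 -> SM14, 0.3 <= p <= 0.7 ->
MIX, else AMBIG; the CLI reports the sensitivity of class fractions to
these edges.

Under Poisson(mu) occupancy with species fraction f, the probability
that an occupied hot spot is spectrally pure is

    P(pure) = (e^{-mu(1-f)} + e^{-mu f} - 2 e^{-mu}) / (1 - e^{-mu}),

which reduces to 2(e^{-mu/2} - e^{-mu})/(1 - e^{-mu}) at f = 1/2
(0.8756 at mu = 0.5). This form was derived here and verified against a
Monte-Carlo simulation (1e6 hot spots) before being trusted; the package
ships both the analytic function and the simulator
(`simulate_bianalyte_histogram()`), and the test suite holds them to
within 3 binomial standard errors across mu in {0.1, 0.5, 1, 2, 5}. At
low occupancy the ratio histogram is edge-dominated (single-molecule
regime); at high occupancy mixtures dominate the center — the package
reproduces both regimes end to end.

## Line shapes, bandwidths, SNR

Single-pixel PESRS spectra show dispersive line shapes from interference
with the plasmonic continuum, so the 680-780 cm^-1 region is fitted with
a Fano profile I = A (q + e)^2/(1 + e^2) + c, e = (nu - nu0)/(Gamma/2).
The reported "bandwidth" is the fitted Gamma, which reduces to the
Lorentzian FWHM as |q| grows — matching how bandwidths are quoted.
Fitting is bounded Levenberg-Marquardt (Gamma in [2, 60] cm^-1, center
inside the window, A >= 0 fixing q's sign convention) from a
deterministic initialization (center at the in-window extremum, width
from its half-height span, offset from the window edges) with three
asymmetry starts; non-convergence sets a failure flag rather than
throwing. Single-band events recover Gamma = 10 cm^-1 (median within
[9, 11] under noise at SNR 30); equal two-band mixtures at the
isotopologue spacing fit systematically broader, so the MIX-vs-SM
bandwidth ordering is asserted qualitatively. The exact mixed-event
median observed in real data depends on the unparameterized mixing
weights and is not asserted numerically.

SNR is reported as the corrected-spectrum peak in the signal window over
the SD in a disjoint noise window — the experiment does not define its
SNR, so this definition is declared and both windows are configurable.
A vanishing noise SD returns a capped sentinel rather than infinity.

## Time traces

Per-pixel band-area traces are classified by binary least-squares
change-point segmentation with a step threshold expressed in sigma
units (default 5 sigma), which makes the classification invariant to
affine intensity rescaling: no significant step and a high mean is
STABLE; one downward step to within 3 sigma of the background level is
BLEACH_STEP; two or more alternating well-separated transitions is
BLINKING; anything else OTHER. The experiment shows such traces but
defines no detector; binary segmentation was chosen as the simplest
method with a testable localization guarantee (noiseless steps located
within 1 frame) and a measured false-blinking rate below 5% on pure
noise. Dwell-time kinetics are intentionally out of scope — at one to
two minutes per frame the data would not constrain rates.

## Problem sizes and determinism

Every stochastic stage derives an independent stream from the global
seed and its stage name, so identical configuration and seed give
bit-identical scenes, cubes and reports (timings aside). The test suite
exercises reduced grids (24-120 px) chosen so each property is tested at
meaningful statistical power; the acceptance script runs the full
200 x 200 x 80 geometry. Intensities are stored as 32-bit values in the
TIFF container and computed in 64-bit memory throughout.

## Known limitations

* The denoiser is a mechanism-faithful collaborative filter, not a port
  of the reference volumetric implementation; absolute denoising gains
  on real data may differ.
* MCR with two highly overlapping components on the 80-channel standard
  axis is near-degenerate when bands shift within the instrument
  resolution; the high-resolution axis is the intended mode for
  isotopologue work, as in the experiment.
* The bianalyte model treats hot spots as independent; aggregate-level
  correlations (shared enhancement) only enter through the generator,
  not the analytic formula.
* Enhancement-factor estimation is provided as a formula
  (`enhancement_factor()`); the measured inputs it needs are
  instrument-specific and no reference value is computed here.
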