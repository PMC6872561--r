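# pesrs

Analysis of hyperspectral plasmon-enhanced stimulated Raman scattering
(PESRS) microscopy at single-molecule sensitivity.

PESRS amplifies stimulated Raman scattering with the near field of
aggregated gold nanoparticles, pushing label-free vibrational detection
down to single molecules with cross-sections around 1e-30 cm^2 — but the
raw data are dominated by a broad non-Raman background (photothermal and
related effects) and single-pixel shot-to-shot noise. This package
implements the full analysis chain that turns raw cubes (200 x 200
pixels x 80 Raman channels, 550-850 cm^-1) into verified single-molecule
statistics:

* **Synthetic scenes** — a ground-truthed generator for
  nanoparticle-aggregate substrates: Poisson hot-spot occupancy,
  log-normal enhancement, isotopologue bands at 733 cm^-1
  (14N-adenine) and 726/724 cm^-1 (15N-adenine) with 10 cm^-1 width,
  polynomial background, Gaussian PSF and detector noise, and
  blinking/bleaching time-lapse dynamics.
* **Baseline** — adaptive iteratively reweighted penalized least squares
  (airPLS) over an O(n) banded Whittaker smoother,
  min_z sum w_i (y_i - z_i)^2 + lambda ||D2 z||^2, applied pixel by
  pixel (compiled).
* **Denoising** — spatial-spectral block matching with collaborative
  DCT-domain hard thresholding and an empirical Wiener refinement pass.
* **Unmixing** — MCR-ALS, D ~ C S with exact non-negative least-squares
  half-steps (support enumeration, monotone objective) and unit-maximum
  spectral normalization, initialized from pure-isotopologue reference
  spectra.
* **Single-molecule statistics** — event selection (band window +
  intensity threshold), the relative-contribution ratio
  p = C14/(C14+C15), its histogram, and the bianalyte Poisson model:
  P(pure | occupied) = (e^(-mu(1-f)) + e^(-mu f) - 2 e^(-mu)) /
  (1 - e^(-mu)), analytic and Monte-Carlo.
* **Line shapes** — Fano fits I = A (q+e)^2/(1+e^2) + c over 680-780
  cm^-1, bandwidth distributions by event class, peak-area maps, SNR.
* **Time traces** — change-point classification of per-pixel band-area
  traces into stable / blinking / single-step bleach.

See `vignettes/pesrs-methods.Rmd` for the models, defaults, and design
rationale.

## Worked example

A bianalyte experiment in the single-molecule regime, end to end:

```r
library(pesrs)

# single-molecule (50 nM-like) bianalyte scene, isotopologue mode
scene_of <- function(f14, mu, hotspots = 6)
  list(grid = c(40L, 40L), n_aggregates = 6L,
       aggregate_radius_um = c(0.8, 1.2),
       hotspots_per_aggregate = hotspots, mu = mu, f14 = f14,
       species_variant = "single",
       enhancement_sdlog = 0.3, weight_sdlog = 0.3)

cfg <- pipeline_config(seed = 41L, preset = "highres",
                       scene = scene_of(0.5, 0.6))
cube <- render_cube(generate_scene(cfg), axis_highres())

# ensemble-regime pure-isotopologue reference acquisitions
refs <- lapply(c(`14NA` = 1, `15NA` = 0), function(f14)
  render_cube(generate_scene(pipeline_config(
    seed = 41L + 1000L * (2 - f14),
    scene = scene_of(f14, 20, hotspots = 8))), axis_highres()))

rep <- run_pipeline(cube, cfg, refs = refs)
rep
#> <pipeline_report> seed 41, hash 9ff44d06
#>   events: 342 of 416 in-window pixels above threshold
#>
#>  SM14  SM15   MIX AMBIG
#>   138    56    94    54
#>   SM14  median Gamma 7.31 cm^-1 (n = 138, failed 0)
#>   SM15  median Gamma 7.72 cm^-1 (n = 56, failed 0)
#>   MIX   median Gamma 15.05 cm^-1 (n = 94, failed 0)
```

Reading the output: of the pixels whose corrected spectrum peaks inside
the 715-745 cm^-1 marker window, 342 exceed the intensity threshold and
become events. At mean occupancy mu = 0.6 most occupied hot spots hold
a single molecule, so the relative-contribution histogram is
edge-dominated: 194 of 342 events are pure 14NA or pure 15NA —
single-molecule events — versus 94 mixtures (mixing here comes from
hot spots sharing a diffraction-limited focus, plus residual unmixing
noise). Mixed events fit with a clearly broader band than
single-molecule events, because a single Fano profile gets stretched
across both isotopologue bands. The analytic expectation for the pure
fraction among occupied hot spots:

```r
bianalyte_pure_event_probability(0.6)
#> [1] 0.851115
```

A command-line front end over the same functions is in
`inst/cli/pesrs.R` (subcommands `simulate`, `denoise`, `baseline`,
`unmix`, `events`, `fitline`, `traces`, `pipeline`).

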