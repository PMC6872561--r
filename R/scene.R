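#' Raman band of one analyte species
#'
#' Bands are parameterized as Fano profiles so that dispersive single-pixel
#' line shapes can be emulated; at the default asymmetry `q = 1000` the
#' profile is a Lorentzian to numerical precision. The generator's band
#' shape is continuum-subtracted so it vanishes far from resonance:
#' `((q + e)^2 / (1 + e^2) - 1) / q^2` with `e = (nu - center)/(fwhm/2)`,
#' which has unit peak height in the Lorentzian limit.
#'
#' @param name species label, e.g. `"14NA"`, `"15NA"`.
#' @param center band center nu0 in cm^-1.
#' @param fwhm band width Gamma in cm^-1 (> 0).
#' @param q Fano asymmetry (non-zero; large magnitude = Lorentzian limit).
#' @param cross_section relative Raman cross-section (scales amplitude).
#' @return An object of class `species_band`.
#' @export
species_band <- function(name, center, fwhm = 10, q = 1000,
                         cross_section = 1) {
  if (fwhm <= 0) stop("fwhm must be > 0")
  if (q == 0) stop("generator bands require non-zero q")
  structure(list(name = name, center = center, fwhm = fwhm, q = q,
                 cross_section = cross_section),
            class = "species_band")
}

#' Default adenine isotopologue bands
#'
#' The 14N-adenine ring-breathing band sits at 733 cm^-1; the
#' 15N-isotopologue band at 726 cm^-1 in ensemble spectra, with a
#' single-pixel variant at 724 cm^-1. Both default to 10 cm^-1 width.
#'
#' @param variant `"ensemble"` (726) or `"single"` (724) for the 15NA band.
#' @return Named list of two [species_band()] objects (`14NA`, `15NA`).
#' @export
default_bands <- function(variant = c("ensemble", "single")) {
  variant <- match.arg(variant)
  list(`14NA` = species_band("14NA", 733),
       `15NA` = species_band("15NA", if (variant == "ensemble") 726 else 724))
}

#' Evaluate a species band on a wavenumber grid
#'
#' @param wn numeric wavenumbers (cm^-1).
#' @param band a [species_band()].
#' @return Intensity profile, unit peak height in the Lorentzian limit.
#' @export
band_profile <- function(wn, band) {
  e <- (wn - band$center) / (band$fwhm / 2)
  band$cross_section * ((band$q + e)^2 / (1 + e^2) - 1) / band$q^2
}

#' Generate a ground-truthed nanoparticle-aggregate scene
#'
#' Emulates a dried colloidal gold substrate: aggregates placed uniformly
#' at random (no wrap-around, kept clear of the image edge so the point
#' spread function does not truncate), hot spots inside each aggregate,
#' per-hot-spot molecule counts drawn Poisson(mu), species assigned 14NA
#' with probability `f14`, per-molecule weights log-normal. Everything is
#' recorded so downstream recovery can be tested against truth.
#'
#' @param config a [pipeline_config()]; the `scene` block supplies all
#'   generator parameters.
#' @param seed integer seed; the scene stream is derived from
#'   `(seed, "scene")`.
#' @return An object of class `ground_truth_scene` with data frames
#'   `aggregates` (row, col, radius_um, background_B, enhancement_G),
#'   `hotspots` (row, col, aggregate, g), `molecules` (hotspot, species,
#'   eta) and the `params` used.
#' @export
generate_scene <- function(config = pipeline_config(), seed = config$seed) {
  sc <- config$scene
  if (sc$mu < 0) stop("mu must be >= 0")
  if (sc$f14 < 0 || sc$f14 > 1) stop("f14 must lie in [0, 1]")
  grid <- as.integer(sc$grid)
  px_per_um <- 1000 / sc$pixel_pitch_nm
  psf_sd_px <- sc$psf_fwhm_nm / 2.355 / sc$pixel_pitch_nm
  margin <- ceiling(max(sc$aggregate_radius_um) * px_per_um +
                      4 * psf_sd_px) + 1L
  if (any(grid - 2L * margin < 1L))
    stop("grid too small for the requested aggregates (need > ",
         2L * margin + 1L, " pixels per side)")
  bands <- default_bands(sc$species_variant)
  with_seed(stage_seed(seed, "scene"), {
    n_agg <- sc$n_aggregates
    agg <- data.frame(
      row = round(runif(n_agg, margin + 1L, grid[1] - margin)),
      col = round(runif(n_agg, margin + 1L, grid[2] - margin)),
      radius_um = runif(n_agg, sc$aggregate_radius_um[1],
                        sc$aggregate_radius_um[2]),
      background_B = sc$background_amplitude * rlnorm(n_agg, 0, 0.3),
      enhancement_G = rlnorm(n_agg, 0, sc$aggregate_sdlog))
    hs <- do.call(rbind, lapply(seq_len(n_agg), function(a) {
      n_hs <- rpois(1L, sc$hotspots_per_aggregate)
      if (n_hs == 0L) return(NULL)
      r_px <- agg$radius_um[a] * px_per_um
      ang <- runif(n_hs, 0, 2 * pi)
      rad <- r_px * sqrt(runif(n_hs))
      data.frame(
        row = pmin(pmax(round(agg$row[a] + rad * sin(ang)), 1L), grid[1]),
        col = pmin(pmax(round(agg$col[a] + rad * cos(ang)), 1L), grid[2]),
        aggregate = a,
        g = agg$enhancement_G[a] * rlnorm(n_hs, 0, sc$enhancement_sdlog))
    }))
    if (is.null(hs))
      hs <- data.frame(row = integer(), col = integer(),
                       aggregate = integer(), g = numeric())
    counts <- if (nrow(hs)) rpois(nrow(hs), sc$mu) else integer()
    mol <- if (sum(counts) > 0L) {
      data.frame(
        hotspot = rep(seq_len(nrow(hs)), counts),
        species = ifelse(rbinom(sum(counts), 1L, sc$f14) == 1L,
                         "14NA", "15NA"),
        eta = rlnorm(sum(counts), 0, sc$weight_sdlog))
    } else {
      data.frame(hotspot = integer(), species = character(),
                 eta = numeric())
    }
    structure(list(aggregates = agg, hotspots = hs, molecules = mol,
                   bands = bands, grid = grid, params = sc, seed = seed),
              class = "ground_truth_scene")
  })
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat(sprintf(
    "<ground_truth_scene> %d x %d px, %d aggregates, %d hot spots, %d molecules (mu = %g, f14 = %g)\n",
    x$grid[1], x$grid[2], nrow(x$aggregates), nrow(x$hotspots),
    nrow(x$molecules), x$params$mu, x$params$f14))
  invisible(x)
}

# Deterministic per-pixel background amplitude field: a floor plus one
# Gaussian bump per aggregate (broad, non-Raman, photothermal-like).
background_amplitude_field <- function(scene) {
  grid <- scene$grid
  px_per_um <- 1000 / scene$params$pixel_pitch_nm
  B <- matrix(scene$params$background_floor, grid[1], grid[2])
  rows <- matrix(seq_len(grid[1]), grid[1], grid[2])
  cols <- matrix(seq_len(grid[2]), grid[1], grid[2], byrow = TRUE)
  ag <- scene$aggregates
  for (a in seq_len(nrow(ag))) {
    r_px <- ag$radius_um[a] * px_per_um
    d2 <- (rows - ag$row[a])^2 + (cols - ag$col[a])^2
    B <- B + ag$background_B[a] * exp(-d2 / (2 * r_px^2))
  }
  B
}

#' Deterministic background field of a scene
#'
#' The broad non-Raman background: per pixel, an amplitude set by local
#' aggregate density times a gentle 2nd-order polynomial across the
#' spectral window (a small per-pixel random tilt emulates slow spectral
#' structure; the background is largely independent of Raman shift). The
#' same `(scene, axis, seed)` always yields the same field, so a
#' noise-free render equals this field exactly when the scene is empty.
#'
#' @param scene a [generate_scene()] result.
#' @param axis a [spectral_axis()].
#' @param seed integer seed (tilt stream derived from `(seed, "background")`).
#' @return A [hyper_cube()] holding the background only.
#' @export
render_background <- function(scene, axis, seed = scene$seed) {
  grid <- scene$grid
  sc <- scene$params
  B <- background_amplitude_field(scene)
  u <- seq(-1, 1, length.out = axis$n_channels)
  tilt <- with_seed(stage_seed(seed, "background"),
                    matrix(rnorm(prod(grid), 0, sc$background_tilt_sd),
                           grid[1], grid[2]))
  data <- array(0, dim = c(grid, axis$n_channels))
  curve <- sc$background_curvature * u^2
  for (k in seq_len(axis$n_channels)) {
    data[, , k] <- B * (1 + tilt * u[k] + curve[k])
  }
  hyper_cube(data, axis, pixel_pitch_nm = sc$pixel_pitch_nm,
             dwell_us = sc$dwell_us)
}

# Separable Gaussian blur of each channel; kernel normalized to unit mass
# so integrated signal is conserved for sources away from the image edge.
blur_channels <- function(data, sd_px) {
  if (sd_px <= 0) return(data)
  r <- ceiling(4 * sd_px)
  k <- exp(-(-r:r)^2 / (2 * sd_px^2))
  k <- k / sum(k)
  d <- dim(data)
  Kr <- conv_band_matrix(d[1], k, r)
  Kc <- conv_band_matrix(d[2], k, r)
  for (ch in seq_len(d[3])) {
    data[, , ch] <- Kr %*% data[, , ch] %*% t(Kc)
  }
  data
}

conv_band_matrix <- function(n, k, r) {
  M <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- seq_len(n)
    j <- idx + o
    ok <- j >= 1 & j <= n
    M[cbind(idx[ok], j[ok])] <- k[o + r + 1]
  }
  M
}

# Per-molecule spectra summed onto their hot-spot pixels (pre-PSF), with
# optional per-molecule on/off states. Signal is strictly linear in pump
# and in Stokes power.
molecule_signal <- function(scene, axis, states = NULL,
                            power_pump = scene$params$power_pump_mw,
                            power_stokes = scene$params$power_stokes_mw) {
  grid <- scene$grid
  data <- array(0, dim = c(grid, axis$n_channels))
  mol <- scene$molecules
  if (nrow(mol) == 0L) return(data)
  sc <- scene$params
  pw <- (power_pump * power_stokes) / (0.15 * 0.15)
  profs <- lapply(scene$bands, function(b) {
    if (b$center < min(axis$wavenumbers) || b$center > max(axis$wavenumbers))
      warning("band ", b$name, " center ", b$center,
              " cm^-1 outside the axis window; band truncated")
    band_profile(axis$wavenumbers, b)
  })
  on <- if (is.null(states)) rep(TRUE, nrow(mol)) else states
  for (m in which(on)) {
    h <- mol$hotspot[m]
    amp <- sc$signal_scale * scene$hotspots$g[h] * mol$eta[m] * pw
    data[scene$hotspots$row[h], scene$hotspots$col[h], ] <-
      data[scene$hotspots$row[h], scene$hotspots$col[h], ] +
      amp * profs[[mol$species[m]]]
  }
  data
}

#' Render a hyperspectral cube from a scene
#'
#' Per-pixel spectrum = broad background + sum over molecules within point
#' spread function reach of `g * eta * (power normalization) * band(nu)`,
#' plus i.i.d. additive Gaussian detector noise. The molecular signal is
#' blurred by a Gaussian PSF of the configured FWHM (unit mass), and is
#' strictly linear in pump power and in Stokes power.
#'
#' @param scene a [generate_scene()] result.
#' @param axis a [spectral_axis()]; presets: [axis_standard()] yields
#'   200 x 200 x 80 cubes, [axis_highres()] 120 channels over 565-850 cm^-1.
#' @param seed integer seed (noise stream from `(seed, "noise")`,
#'   background tilt from `(seed, "background")`).
#' @param noise_sigma additive Gaussian noise SD; defaults to the scene's.
#' @param power_pump_mw,power_stokes_mw laser powers (mW).
#' @param states optional logical per-molecule on/off vector (used by the
#'   time-lapse renderer).
#' @param background optional precomputed [render_background()] cube; the
#'   time-lapse renderer passes one so the substrate is static over frames.
#' @return A [hyper_cube()].
#' @export
render_cube <- function(scene, axis = axis_standard(), seed = scene$seed,
                        noise_sigma = scene$params$noise_sigma,
                        power_pump_mw = scene$params$power_pump_mw,
                        power_stokes_mw = scene$params$power_stokes_mw,
                        states = NULL, background = NULL) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  bg <- if (is.null(background)) render_background(scene, axis, seed = seed)
        else background
  sig <- molecule_signal(scene, axis, states = states,
                         power_pump = power_pump_mw,
                         power_stokes = power_stokes_mw)
  sd_px <- scene$params$psf_fwhm_nm / 2.355 / scene$params$pixel_pitch_nm
  sig <- blur_channels(sig, sd_px)
  data <- bg$data + sig
  if (noise_sigma > 0) {
    data <- data + with_seed(stage_seed(seed, "noise"),
                             array(rnorm(length(data), 0, noise_sigma),
                                   dim = dim(data)))
  }
  hyper_cube(data, axis, pixel_pitch_nm = scene$params$pixel_pitch_nm,
             dwell_us = scene$params$dwell_us)
}

#' Blinking/bleaching dynamics parameters
#'
#' @param blink_on probability per frame of an off emitter turning on.
#' @param blink_off probability per frame of an on emitter turning off.
#' @param bleach_prob probability per frame of irreversible one-step loss.
#' @param stable_fraction fraction of molecules exempt from dynamics.
#' @return An object of class `dynamics_params`.
#' @export
dynamics_params <- function(blink_on = 0.2, blink_off = 0.2,
                            bleach_prob = 0.02, stable_fraction = 0) {
  p <- c(blink_on, blink_off, bleach_prob, stable_fraction)
  if (any(p < 0 | p > 1)) stop("dynamics probabilities must lie in [0, 1]")
  structure(list(blink_on = blink_on, blink_off = blink_off,
                 bleach_prob = bleach_prob,
                 stable_fraction = stable_fraction),
            class = "dynamics_params")
}

# Per-molecule on/off trajectories: stable molecules stay on; the rest
# follow a two-state telegraph initialized from its stationary
# distribution, with an independent absorbing bleach each frame.
timelapse_states <- function(scene, n_frames, dynamics, seed) {
  n_mol <- nrow(scene$molecules)
  with_seed(stage_seed(seed, "dynamics"), {
    st <- matrix(TRUE, max(n_mol, 1L), n_frames)
    if (n_mol > 0L) {
      stable <- runif(n_mol) < dynamics$stable_fraction
      p_on <- if (dynamics$blink_on + dynamics$blink_off > 0)
        dynamics$blink_on / (dynamics$blink_on + dynamics$blink_off) else 1
      cur <- ifelse(stable, TRUE, runif(n_mol) < p_on)
      bleached <- rep(FALSE, n_mol)
      for (t in seq_len(n_frames)) {
        st[, t] <- cur & !bleached
        flip <- !stable & ifelse(cur,
                                 runif(n_mol) < dynamics$blink_off,
                                 runif(n_mol) < dynamics$blink_on)
        cur <- xor(cur, flip)
        bleached <- bleached |
          (!stable & runif(n_mol) < dynamics$bleach_prob)
      }
    }
    st
  })
}

#' Render a time-lapse stack with single-molecule dynamics
#'
#' Each molecule carries a state trajectory: stable (always on), two-state
#' telegraph blinking (initialized from the stationary distribution), and
#' irreversible one-step bleaching. Frames are rendered from the
#' instantaneous on-states over a static background; noise is redrawn per
#' frame. Trajectories are recorded as truth.
#'
#' @param scene a [generate_scene()] result.
#' @param axis a [spectral_axis()].
#' @param n_frames number of frames (>= 2).
#' @param dynamics a [dynamics_params()].
#' @param seed integer seed.
#' @return An object of class `pesrs_timelapse`: list with `frames` (list
#'   of [hyper_cube()], `frame_index` set) and `states` (molecules x frames
#'   logical matrix).
#' @export
render_timelapse <- function(scene, axis = axis_standard(), n_frames,
                             dynamics = dynamics_params(),
                             seed = scene$seed) {
  if (n_frames < 2L) stop("n_frames must be >= 2")
  stopifnot(inherits(dynamics, "dynamics_params"))
  n_mol <- nrow(scene$molecules)
  states <- timelapse_states(scene, n_frames, dynamics, seed)
  bg <- render_background(scene, axis, seed = seed)
  frames <- lapply(seq_len(n_frames), function(t) {
    fr <- render_cube(scene, axis, seed = stage_seed(seed, paste0("frame", t)),
                      states = if (n_mol > 0L) states[, t] else NULL,
                      background = bg)
    fr$frame_index <- t
    fr
  })
  structure(list(frames = frames,
                 states = if (n_mol > 0L) states else
                   matrix(logical(), 0L, n_frames),
                 dynamics = dynamics, scene = scene),
            class = "pesrs_timelapse")
}

#' @export
print.pesrs_timelapse <- function(x, ...) {
  cat(sprintf("<pesrs_timelapse> %d frames, %d molecules\n",
              length(x$frames), nrow(x$states)))
  invisible(x)
}

#' Serialize a ground-truth scene to JSON
#'
#' @param scene a [generate_scene()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  x <- list(aggregates = scene$aggregates, hotspots = scene$hotspots,
            molecules = scene$molecules, grid = scene$grid,
            params = scene$params, seed = scene$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
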