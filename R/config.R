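#' Pipeline configuration
#'
#' One nested list holds every stage parameter plus the global random seed.
#' Each stochastic stage derives its own independent stream from
#' `(seed, stage name)` (see [stage_seed()]) so stages are individually
#' reproducible. The configuration serializes losslessly to JSON and YAML.
#'
#' Defaults encode the study conditions the generator emulates: 200 x 200
#' pixel cubes at 150 nm pitch, 80 channels over 550-850 cm^-1 (preset
#' `"standard"`) or 120 channels over 565-850 cm^-1 (`"highres"`), adenine
#' ring-breathing bands at 733 (14NA) and 726/724 (15NA) cm^-1 with 10
#' cm^-1 width, Poisson hot-spot occupancy, and an event threshold of 0.03
#' on the normalized intensity scale with the 715-745 cm^-1 band window.
#'
#' @param ... named overrides; nested lists are merged element-wise into
#'   the defaults (e.g. `pipeline_config(scene = list(mu = 2))`).
#' @return An object of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(seed = 7, scene = list(mu = 0.5, f14 = 0.5))
#' cfg$scene$mu
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    preset = "standard",
    scene = list(
      grid = c(200L, 200L),
      n_aggregates = 10L,
      aggregate_radius_um = c(0.5, 1.5),
      hotspots_per_aggregate = 6,
      mu = 1,
      f14 = 0.5,
      species_variant = "ensemble",
      background_amplitude = 10,
      background_floor = 0.5,
      background_curvature = -0.1,
      background_tilt_sd = 0.05,
      signal_scale = 8,
      aggregate_sdlog = 0.5,
      enhancement_sdlog = 0.7,
      weight_sdlog = 0.4,
      noise_sigma = 0.12,
      psf_fwhm_nm = 400,
      pixel_pitch_nm = 150,
      dwell_us = 10,
      power_pump_mw = 0.15,
      power_stokes_mw = 0.15
    ),
    dynamics = list(
      blink_on = 0.2,
      blink_off = 0.2,
      bleach_prob = 0.02,
      stable_fraction = 0
    ),
    baseline = list(lambda = 1000, max_iter = 30L, tol = 0.001),
    denoise = list(
      spatial = 4L, spectral = 16L, search = 12L, group = 16L,
      kappa = 2.7, sigma = "auto", wiener = TRUE,
      step_spatial = 3L, step_spectral = 8L
    ),
    mcr = list(k = 2L, max_iter = 50L, tol = 1e-4, augment_refs = TRUE),
    events = list(
      tau = 0.03, window = c(715, 745),
      sm_edges = c(0.1, 0.9), mix_band = c(0.3, 0.7), n_bins = 20L
    ),
    fano = list(window = c(680, 780)),
    order = c("denoise", "baseline")
  )
  cfg <- merge_config(defaults, list(...))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

merge_config <- function(base, override) {
  if (length(override) == 0L) return(base)
  nm <- names(override)
  if (is.null(nm) || any(nm == ""))
    stop("configuration overrides must be named")
  for (n in nm) {
    if (is.list(override[[n]]) && is.list(base[[n]])) {
      base[[n]] <- merge_config(base[[n]], override[[n]])
    } else {
      base[[n]] <- override[[n]]
    }
  }
  base
}

validate_config <- function(cfg) {
  sc <- cfg$scene
  if (sc$mu < 0) stop("scene$mu must be >= 0")
  if (sc$f14 < 0 || sc$f14 > 1) stop("scene$f14 must lie in [0, 1]")
  pos <- c(baseline_lambda = cfg$baseline$lambda,
           denoise_kappa = cfg$denoise$kappa,
           events_tau = cfg$events$tau,
           mcr_tol = cfg$mcr$tol,
           noise_check = 1 + sc$noise_sigma)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("positive-valued configuration parameter out of range: ",
         paste(names(pos)[!is.finite(pos) | pos <= 0], collapse = ", "))
  dy <- unlist(cfg$dynamics)
  if (any(dy < 0 | dy > 1))
    stop("dynamics probabilities/rates must lie in [0, 1]")
  invisible(cfg)
}

#' Read and write pipeline configurations
#'
#' Format is chosen by file extension: `.json` via jsonlite, `.yaml`/`.yml`
#' via the yaml package. Round trips are lossless.
#'
#' @param cfg a [pipeline_config()].
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_config` returns a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  x <- unclass(cfg)
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    writeLines(yaml::as.yaml(x, precision = 15L), path)
  } else stop("unsupported config format: .", ext)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else stop("unsupported config format: .", ext)
  do.call(pipeline_config, x)
}
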