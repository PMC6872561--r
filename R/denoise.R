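#' Robust noise estimate for a hyperspectral cube
#'
#' Estimates the additive Gaussian noise SD from the median absolute
#' deviation of second differences along the spectral axis; smooth
#' spectral structure contributes almost nothing to the high-pass
#' residual, so the estimate is insensitive to signal and to constant
#' offsets. Scaling: second differences of i.i.d. Gaussian noise have
#' SD `sigma * sqrt(6)`, and MAD/0.6745 estimates an SD.
#'
#' @param cube a [hyper_cube()] (>= 8 channels).
#' @return Positive noise SD estimate (0, with a warning, for a constant
#'   cube).
#' @export
estimate_noise_sigma <- function(cube) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$data)
  if (d[3] < 8L) stop("need at least 8 channels to estimate noise")
  m <- cube_matrix(cube)
  e <- m[, 3:d[3], drop = FALSE] - 2 * m[, 2:(d[3] - 1), drop = FALSE] +
    m[, 1:(d[3] - 2), drop = FALSE]
  s <- median(abs(e)) / 0.6745 / sqrt(6)
  if (s == 0) warning("constant cube: noise estimate is 0")
  s
}

#' Denoiser parameters
#'
#' @param spatial spatial patch side in pixels (default 4).
#' @param spectral spectral patch depth in channels (default 16).
#' @param search spatial search window radius in pixels (default 12).
#' @param group maximum number of patches per group (default 16).
#' @param kappa hard-threshold multiplier on sigma (default 2.7).
#' @param sigma `"auto"` or a fixed positive noise SD.
#' @param wiener run the empirical-Wiener refinement pass (default TRUE).
#' @param step_spatial,step_spectral reference-patch strides.
#' @return An object of class `denoise_params`.
#' @export
denoise_params <- function(spatial = 4L, spectral = 16L, search = 12L,
                           group = 16L, kappa = 2.7, sigma = "auto",
                           wiener = TRUE, step_spatial = 3L,
                           step_spectral = 8L) {
  if (spatial < 2L || spectral < 2L) stop("patch sizes must be >= 2")
  if (kappa <= 0) stop("kappa must be > 0")
  structure(list(spatial = as.integer(spatial),
                 spectral = as.integer(spectral),
                 search = as.integer(search), group = as.integer(group),
                 kappa = kappa, sigma = sigma, wiener = isTRUE(wiener),
                 step_spatial = as.integer(step_spatial),
                 step_spectral = as.integer(step_spectral)),
            class = "denoise_params")
}

#' Block-matching collaborative denoising of a cube
#'
#' Groups mutually similar spatial-spectral patches (similarity measured
#' on a coarse-prefiltered cube so matching is not noise-driven), applies
#' a separable orthonormal DCT across all four group dimensions, hard
#' thresholds the coefficients at `kappa * sigma`, and, if enabled,
#' refines with an empirical Wiener pass using the first pass as pilot.
#' Patches are aggregated back with weights inversely proportional to the
#' retained-coefficient count. Output shape and axis match the input;
#' the spectral dimension is never split across groups.
#'
#' @param cube a [hyper_cube()].
#' @param params a [denoise_params()].
#' @param sigma optional noise SD override (otherwise `params$sigma`,
#'   with `"auto"` estimated by [estimate_noise_sigma()]).
#' @return The denoised [hyper_cube()].
#' @export
bm_denoise <- function(cube, params = denoise_params(), sigma = NULL) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(params, "denoise_params"))
  d <- dim(cube$data)
  if (params$spatial > min(d[1:2]))
    stop("spatial patch (", params$spatial, ") larger than cube extents")
  spectral <- min(params$spectral, d[3])
  if (is.null(sigma)) sigma <- params$sigma
  if (identical(sigma, "auto")) sigma <- estimate_noise_sigma(cube)
  sigma <- as.numeric(sigma)
  if (!is.finite(sigma) || sigma < 0)
    stop("sigma must be a non-negative number or 'auto'")
  out <- bm_denoise_cpp(as.numeric(cube$data), as.integer(d),
                        params$spatial, spectral, params$search,
                        params$group, params$kappa, sigma, params$wiener,
                        params$step_spatial,
                        min(params$step_spectral, spectral))
  hyper_cube(array(out, dim = d), cube$axis,
             pixel_pitch_nm = cube$pixel_pitch_nm,
             dwell_us = cube$dwell_us, frame_index = cube$frame_index)
}
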