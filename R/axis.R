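#' Calibrated Raman-shift axis
#'
#' A spectral axis holds the wavenumber calibration of a hyperspectral cube:
#' a strictly increasing vector of Raman shifts (cm^-1) plus the instrument
#' spectral resolution as metadata. Descending input is flipped with a
#' warning so that the package keeps a single ascending internal convention.
#'
#' @param wavenumbers numeric vector of Raman shifts in cm^-1, strictly
#'   monotone (ascending preferred; descending is flipped with a warning).
#' @param resolution_fwhm instrument line width (cm^-1), metadata only.
#' @return An object of class `spectral_axis` with fields `wavenumbers`,
#'   `n_channels` and `resolution_fwhm`.
#' @examples
#' ax <- spectral_axis(seq(550, 850, length.out = 80), resolution_fwhm = 13.7)
#' ax$n_channels
#' @export
spectral_axis <- function(wavenumbers, resolution_fwhm = NA_real_) {
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) < 1L || any(!is.finite(wavenumbers)))
    stop("wavenumbers must be a non-empty finite numeric vector")
  if (length(wavenumbers) > 1L) {
    d <- diff(wavenumbers)
    if (all(d < 0)) {
      warning("descending wavenumber axis flipped to ascending")
      wavenumbers <- rev(wavenumbers)
    } else if (any(d <= 0)) {
      stop("wavenumbers must be strictly monotone")
    }
  }
  structure(
    list(wavenumbers = wavenumbers,
         n_channels = length(wavenumbers),
         resolution_fwhm = as.numeric(resolution_fwhm)),
    class = "spectral_axis")
}

#' Acquisition presets for the spectral axis
#'
#' `axis_standard()` is the routine imaging mode: 80 Raman channels spanning
#' 550 to 850 cm^-1 at 13.7 cm^-1 spectral resolution. `axis_highres()` is
#' the isotopologue-resolving mode: 120 channels from 565 to 850 cm^-1 at
#' about 7 cm^-1 resolution, used to separate the 733 and 726 cm^-1
#' adenine ring-breathing bands.
#'
#' @return A `spectral_axis`.
#' @export
axis_standard <- function() {
  spectral_axis(seq(550, 850, length.out = 80L), resolution_fwhm = 13.7)
}

#' @rdname axis_standard
#' @export
axis_highres <- function() {
  spectral_axis(seq(565, 850, length.out = 120L), resolution_fwhm = 7)
}

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf("<spectral_axis> %d channels, %.1f-%.1f cm^-1 (fwhm %.1f)\n",
              x$n_channels, min(x$wavenumbers), max(x$wavenumbers),
              x$resolution_fwhm))
  invisible(x)
}

axis_equal <- function(a, b, tol = 1e-9) {
  a$n_channels == b$n_channels &&
    max(abs(a$wavenumbers - b$wavenumbers)) <= tol
}

#' Channel indices inside a wavenumber window
#'
#' @param axis a `spectral_axis`.
#' @param window length-2 numeric `c(lo, hi)` in cm^-1.
#' @return integer vector of channel indices.
#' @keywords internal
window_channels <- function(axis, window) {
  stopifnot(length(window) == 2L)
  window <- sort(as.numeric(window))
  idx <- which(axis$wavenumbers >= window[1] & axis$wavenumbers <= window[2])
  if (length(idx) == 0L)
    stop("window [", window[1], ", ", window[2],
         "] does not overlap the spectral axis")
  idx
}
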