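#' Hyperspectral cube
#'
#' The universal currency of the pipeline: a (row, column, channel) array of
#' real intensities with a calibrated wavenumber axis and acquisition
#' metadata. All stage entry points accept and return this type so stages
#' compose in the acquisition-order pipeline (denoise, baseline, unmix,
#' statistics).
#'
#' @param data numeric array indexed (row, column, channel); finite.
#' @param axis a [spectral_axis()]; its channel count must match `dim(data)[3]`.
#' @param pixel_pitch_nm scan step in nm (default 150).
#' @param dwell_us pixel dwell time in microseconds, metadata (default 10).
#' @param frame_index optional integer frame number for time-lapse stacks.
#' @return An object of class `hyper_cube`.
#' @export
hyper_cube <- function(data, axis, pixel_pitch_nm = 150, dwell_us = 10,
                       frame_index = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array (row, column, channel)")
  if (!inherits(axis, "spectral_axis")) stop("axis must be a spectral_axis")
  if (dim(data)[3] != axis$n_channels)
    stop("channel dimension (", dim(data)[3], ") does not match axis (",
         axis$n_channels, " channels)")
  if (any(dim(data)[1:2] < 1L)) stop("row/column extents must be >= 1")
  if (!all(is.finite(data))) stop("cube data must be finite")
  storage.mode(data) <- "double"
  structure(
    list(data = data, axis = axis,
         pixel_pitch_nm = as.numeric(pixel_pitch_nm),
         dwell_us = as.numeric(dwell_us),
         frame_index = if (is.null(frame_index)) NULL else
           as.integer(frame_index)),
    class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<hyper_cube> %d x %d pixels x %d channels, %.0f nm pitch%s\n",
    d[1], d[2], d[3], x$pixel_pitch_nm,
    if (is.null(x$frame_index)) "" else sprintf(", frame %d", x$frame_index)))
  print(x$axis)
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$data)

#' Single spectrum
#'
#' @param intensity numeric vector, one value per channel.
#' @param axis a [spectral_axis()].
#' @param origin optional `c(row, col)` pixel coordinate of the spectrum.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(intensity, axis, origin = NULL) {
  intensity <- as.numeric(intensity)
  if (!inherits(axis, "spectral_axis")) stop("axis must be a spectral_axis")
  if (length(intensity) != axis$n_channels)
    stop("intensity length does not match axis")
  if (any(!is.finite(intensity))) stop("intensity must be finite")
  structure(list(intensity = intensity, axis = axis,
                 origin = if (is.null(origin)) NULL else as.integer(origin)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d channels, %.1f-%.1f cm^-1%s\n",
              x$axis$n_channels, min(x$axis$wavenumbers),
              max(x$axis$wavenumbers),
              if (is.null(x$origin)) "" else
                sprintf(", pixel (%d, %d)", x$origin[1], x$origin[2])))
  invisible(x)
}

#' Extract the spectrum at one pixel of a cube
#'
#' @param cube a [hyper_cube()].
#' @param row,col 1-based pixel indices.
#' @return A [spectrum()] with `origin` set.
#' @export
cube_spectrum <- function(cube, row, col) {
  d <- dim(cube$data)
  if (row < 1L || row > d[1] || col < 1L || col > d[2])
    stop("pixel (", row, ", ", col, ") outside the ", d[1], " x ", d[2],
         " grid")
  spectrum(cube$data[row, col, ], cube$axis, origin = c(row, col))
}

#' Flatten a cube to a pixels-by-channels matrix (and back)
#'
#' Pixel order is column-major over the image grid (R's native array
#' order), so `cube_matrix` and `matrix_cube` are exact inverses.
#'
#' @param cube a [hyper_cube()].
#' @return `cube_matrix`: numeric matrix (npixels x nchannels).
#' @export
cube_matrix <- function(cube) {
  d <- dim(cube$data)
  matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
}

#' @rdname cube_matrix
#' @param m pixels-by-channels matrix.
#' @param like template `hyper_cube` supplying grid shape, axis and metadata.
#' @export
matrix_cube <- function(m, like) {
  d <- dim(like$data)
  stopifnot(nrow(m) == d[1] * d[2], ncol(m) == d[3])
  hyper_cube(array(m, dim = d), like$axis,
             pixel_pitch_nm = like$pixel_pitch_nm,
             dwell_us = like$dwell_us, frame_index = like$frame_index)
}
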