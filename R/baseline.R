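#' Whittaker smoother with channel weights
#'
#' Returns the unique minimizer z of
#' `sum_i w_i (y_i - z_i)^2 + lambda * sum_j (z_{j-1} - 2 z_j + z_{j+1})^2`,
#' the penalized least-squares smoother at the heart of airPLS baseline
#' estimation. The normal equations are pentadiagonal and are solved by a
#' banded Cholesky factorization in O(n).
#'
#' @param y numeric vector (finite, length >= 3).
#' @param w non-negative weights, same length, at least 3 positive entries.
#' @param lambda positive smoothness penalty.
#' @return Numeric vector z of the same length.
#' @examples
#' y <- 2 + 0.5 * (1:40)      # affine input lies in the penalty null space
#' max(abs(whittaker_smooth(y, rep(1, 40), 100) - y))
#' @export
whittaker_smooth <- function(y, w, lambda) {
  y <- as.numeric(y); w <- as.numeric(w)
  if (length(y) != length(w)) stop("y and w must have equal length")
  if (length(y) < 3L) stop("need at least 3 channels")
  if (any(!is.finite(y)) || any(!is.finite(w))) stop("non-finite input")
  if (any(w < 0)) stop("weights must be non-negative")
  if (sum(w > 0) < 3L) stop("need at least 3 positive weights")
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  whittaker_cpp(y, w, lambda)
}

#' airPLS baseline estimation for a single spectrum
#'
#' Adaptive iteratively reweighted penalized least squares: starting from
#' uniform weights, the spectrum is Whittaker-smoothed, channels above the
#' running fit (the Raman peaks) are given zero weight, channels below it
#' are up-weighted exponentially, and the fit repeats until the summed
#' negative residual falls below `tol` times the total absolute signal.
#' The two boundary channels are pinned to the maximum weight so the
#' baseline stays anchored at the window edges. The broad non-Raman
#' background (photothermal and related effects in PESRS) is recovered as
#' the baseline; `corrected + baseline` reconstructs the input exactly.
#'
#' @param y numeric spectrum (finite, length >= 5) or a [spectrum()].
#' @param lambda smoothness penalty (default 1000 for an 80-channel
#'   window).
#' @param max_iter maximum number of reweighting iterations (default 30).
#' @param tol termination ratio on `|d^-|_1 / |y|_1` (default 0.001).
#' @return An object of class `baseline_result`: `baseline`, `corrected`,
#'   `weights`, `iterations`, `converged`, `term_ratio`, `lambda`.
#' @export
airpls <- function(y, lambda = 1000, max_iter = 30L, tol = 0.001) {
  if (inherits(y, "spectrum")) y <- y$intensity
  y <- as.numeric(y)
  if (length(y) < 5L) stop("need at least 5 channels")
  if (any(!is.finite(y))) stop("non-finite input")
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  r <- airpls_cpp(y, lambda, as.integer(max_iter), tol)
  structure(list(baseline = r$baseline, corrected = y - r$baseline,
                 weights = r$weights, iterations = r$iterations,
                 converged = r$converged, term_ratio = r$term_ratio,
                 lambda = lambda),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf(
    "<baseline_result> %d channels, %d iterations, %sconverged (ratio %.2g, lambda %g)\n",
    length(x$baseline), x$iterations, if (x$converged) "" else "NOT ",
    x$term_ratio, x$lambda))
  invisible(x)
}

#' Pixel-by-pixel baseline subtraction over a cube
#'
#' Runs [airpls()] independently on every pixel spectrum. Per-pixel
#' convergence flags and iteration counts are returned; a pixel that hits
#' `max_iter` is flagged, not fatal.
#'
#' @param cube a [hyper_cube()].
#' @inheritParams airpls
#' @return A list of class `cube_baseline`: `corrected` and `baseline`
#'   cubes (`corrected + baseline` equals the input exactly), `iterations`
#'   matrix, `converged` logical matrix.
#' @export
subtract_baseline_cube <- function(cube, lambda = 1000, max_iter = 30L,
                                   tol = 0.001) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  d <- dim(cube$data)
  r <- airpls_cube_cpp(as.numeric(cube$data), as.integer(d), lambda,
                       as.integer(max_iter), tol)
  bl <- array(r$baseline, dim = d)
  structure(list(
    corrected = hyper_cube(cube$data - bl, cube$axis,
                           pixel_pitch_nm = cube$pixel_pitch_nm,
                           dwell_us = cube$dwell_us,
                           frame_index = cube$frame_index),
    baseline = hyper_cube(bl, cube$axis,
                          pixel_pitch_nm = cube$pixel_pitch_nm,
                          dwell_us = cube$dwell_us,
                          frame_index = cube$frame_index),
    iterations = matrix(r$iterations, d[1], d[2]),
    converged = matrix(r$converged, d[1], d[2]),
    lambda = lambda), class = "cube_baseline")
}

#' @export
print.cube_baseline <- function(x, ...) {
  cat(sprintf("<cube_baseline> %d x %d pixels, %.1f%% converged, lambda %g\n",
              nrow(x$converged), ncol(x$converged),
              100 * mean(x$converged), x$lambda))
  invisible(x)
}
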