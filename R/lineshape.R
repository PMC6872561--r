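#' Fano line-shape model
#'
#' `I(nu) = A (q + e)^2 / (1 + e^2) + c` with
#' `e = (nu - nu0) / (Gamma / 2)`. As `|q| -> Inf` with `A q^2` held
#' fixed the profile tends to a Lorentzian of FWHM `Gamma`; at `q = 0` it
#' is a symmetric antiresonance dip reaching `c` at `nu0`. Interference
#' between the vibrational resonance and the plasmonic continuum gives
#' PESRS spectra exactly this family of dispersive shapes.
#'
#' @param nu wavenumbers (cm^-1).
#' @param nu0 center (cm^-1).
#' @param gamma width Gamma (cm^-1, > 0); reported as the bandwidth.
#' @param q asymmetry (dimensionless).
#' @param A amplitude.
#' @param c constant offset.
#' @return Intensity vector.
#' @export
fano_model <- function(nu, nu0, gamma, q, A, c) {
  if (gamma <= 0) stop("gamma must be > 0")
  e <- (nu - nu0) / (gamma / 2)
  A * (q + e)^2 / (1 + e^2) + c
}

#' Fit a Fano line shape over a spectral window
#'
#' Nonlinear least squares of [fano_model()] over the fitting window
#' (default 680-780 cm^-1, bracketing the adenine ring-breathing region).
#' Initialization: center at the in-window extremum, width from the
#' extremum's half-height span, offset from the window edges; several
#' asymmetry starts are tried and the best by residual kept. Bounds:
#' `gamma` in [2, 60] cm^-1, center inside the window, `A >= 0` (which
#' fixes the sign convention of `q`). Never throws on non-convergence;
#' inspect `success`.
#'
#' @param spec a [spectrum()], or a numeric vector with `axis` supplied.
#' @param window fit window in cm^-1 (default `c(680, 780)`).
#' @param axis a [spectral_axis()] when `spec` is a bare vector.
#' @return An object of class `fano_fit`: `center`, `gamma`, `q`,
#'   `amplitude`, `offset`, `rms`, `success`, `n_points`.
#' @export
fit_fano <- function(spec, window = c(680, 780), axis = NULL) {
  if (inherits(spec, "spectrum")) {
    y <- spec$intensity
    axis <- spec$axis
  } else {
    y <- as.numeric(spec)
    if (is.null(axis)) stop("supply an axis for a bare intensity vector")
  }
  idx <- window_channels(axis, window)
  if (length(idx) < 8L) stop("need at least 8 channels inside the window")
  nu <- axis$wavenumbers[idx]
  yy <- y[idx]
  fail <- structure(list(center = NA_real_, gamma = NA_real_, q = NA_real_,
                         amplitude = NA_real_, offset = NA_real_,
                         rms = NA_real_, success = FALSE,
                         n_points = length(idx)),
                    class = "fano_fit")
  if (max(yy) - min(yy) <= .Machine$double.eps * max(1, max(abs(yy))))
    return(fail)
  c0 <- mean(c(head(yy, 2L), tail(yy, 2L)))
  i0 <- which.max(abs(yy - c0))
  nu0_0 <- nu[i0]
  h <- yy[i0] - c0
  half <- abs(yy - c0) >= abs(h) / 2
  gamma0 <- min(max(diff(range(nu[half])), 2), 60)
  if (!is.finite(gamma0) || gamma0 <= 0) gamma0 <- 10
  lower <- c(min(nu), 2, -1e4, 0, -Inf)
  upper <- c(max(nu), 60, 1e4, Inf, Inf)
  best <- NULL
  for (q0 in c(50, 8, -8)) {
    A0 <- max(abs(h) / q0^2, 1e-12)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = list(nu0 = nu0_0, gamma = gamma0, q = q0, A = A0, c = c0),
        lower = lower, upper = upper,
        fn = function(p) fano_model(nu, p$nu0, p$gamma, p$q, p$A, p$c) - yy,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) return(fail)
  p <- as.list(coef(best))
  if (any(!is.finite(unlist(p)))) return(fail)
  structure(list(center = p$nu0, gamma = p$gamma, q = p$q,
                 amplitude = p$A, offset = p$c,
                 rms = sqrt(best$deviance / length(idx)),
                 success = TRUE, n_points = length(idx)),
            class = "fano_fit")
}

#' @export
print.fano_fit <- function(x, ...) {
  if (!x$success) {
    cat("<fano_fit> failed\n")
  } else {
    cat(sprintf(
      "<fano_fit> center %.1f cm^-1, Gamma %.2f cm^-1, q %.3g (rms %.3g)\n",
      x$center, x$gamma, x$q, x$rms))
  }
  invisible(x)
}

#' Bandwidth distributions by event class
#'
#' Fits a Fano line shape to every classified event's corrected spectrum
#' and collects the fitted widths per class. Single-molecule events carry
#' one band and recover the intrinsic bandwidth; mixed events carry two
#' closely spaced isotopologue bands that a single profile fits with an
#' inflated width, so the MIX median exceeds the SM medians.
#'
#' @param table a classified `event_table`.
#' @param cube the corrected [hyper_cube()] the events came from.
#' @param window fit window (default `c(680, 780)` cm^-1).
#' @param classes classes to summarize.
#' @return List of class `bandwidth_by_class`: per class, `gamma`
#'   (successful fits), `median`, `n_failed`.
#' @export
bandwidth_by_class <- function(table, cube, window = c(680, 780),
                               classes = c("SM14", "SM15", "MIX")) {
  stopifnot(inherits(table, "event_table"), inherits(cube, "hyper_cube"))
  if (all(is.na(table$class))) stop("classify the events first")
  out <- lapply(classes, function(cl) {
    rows <- which(table$class == cl)
    gam <- numeric(0)
    failed <- 0L
    for (r in rows) {
      f <- fit_fano(cube_spectrum(cube, table$row[r], table$col[r]),
                    window = window)
      if (f$success) gam <- c(gam, f$gamma) else failed <- failed + 1L
    }
    list(gamma = gam,
         median = if (length(gam)) median(gam) else NA_real_,
         n_failed = failed)
  })
  names(out) <- classes
  structure(out, class = "bandwidth_by_class")
}

#' @export
print.bandwidth_by_class <- function(x, ...) {
  for (cl in names(x)) {
    cat(sprintf("  %-5s median Gamma %.2f cm^-1 (n = %d, failed %d)\n",
                cl, x[[cl]]$median, length(x[[cl]]$gamma), x[[cl]]$n_failed))
  }
  invisible(x)
}

#' Peak-area image over a band window
#'
#' Per-pixel trapezoidal integral of the corrected spectrum over the band
#' window. Negative areas are preserved (not clipped) so the noise floor
#' stays honest.
#'
#' @param cube corrected [hyper_cube()].
#' @param window band window in cm^-1 (default `c(715, 745)`).
#' @return Numeric image matrix aligned with the cube grid.
#' @export
peak_area_map <- function(cube, window = c(715, 745)) {
  stopifnot(inherits(cube, "hyper_cube"))
  idx <- window_channels(cube$axis, window)
  if (length(idx) < 2L) stop("window holds fewer than 2 channels")
  wn <- cube$axis$wavenumbers[idx]
  dx <- diff(wn)
  tw <- numeric(length(idx))
  tw[-length(tw)] <- tw[-length(tw)] + dx / 2
  tw[-1] <- tw[-1] + dx / 2
  m <- cube_matrix(cube)[, idx, drop = FALSE]
  d <- dim(cube$data)
  matrix(m %*% tw, d[1], d[2])
}

#' Signal-to-noise ratio of a corrected spectrum
#'
#' Peak height in the signal window divided by the standard deviation in
#' a disjoint noise window. This is the working SNR definition for
#' single-pixel spectra; both windows are configurable.
#'
#' @param spec a [spectrum()].
#' @param signal_window,noise_window disjoint windows in cm^-1.
#' @param cap sentinel returned when the noise SD underflows (default
#'   1e9).
#' @return SNR (dimensionless).
#' @export
snr <- function(spec, signal_window = c(715, 745),
                noise_window = c(560, 680), cap = 1e9) {
  stopifnot(inherits(spec, "spectrum"))
  si <- window_channels(spec$axis, signal_window)
  ni <- window_channels(spec$axis, noise_window)
  if (length(intersect(si, ni)) > 0L)
    stop("signal and noise windows must be disjoint")
  s <- sd(spec$intensity[ni])
  if (!is.finite(s) || s == 0) stop("zero-variance noise window")
  peak <- max(spec$intensity[si])
  min(peak / s, cap)
}
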