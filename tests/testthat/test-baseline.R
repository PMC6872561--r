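# Dense-matrix oracle for the Whittaker smoother: explicit normal
# equations (W + lambda D'D) z = W y solved with base R.
dense_whittaker <- function(y, w, lambda) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  solve(diag(w) + lambda * crossprod(D), w * y)
}

test_that("whittaker smoother reproduces affine input and the no-penalty limit", {
  y <- 2 + 0.7 * (0:39)
  w <- runif(40, 0.5, 2)
  expect_lt(max(abs(whittaker_smooth(y, w, 1e6) - y)), 1e-6)
  y2 <- rnorm(40)
  expect_lt(max(abs(whittaker_smooth(y2, rep(1, 40), 1e-10) - y2)), 1e-5)
})

test_that("banded solver matches the dense oracle to 1e-8", {
  set.seed(1)
  for (rep in 1:5) {
    y <- rnorm(40)
    w <- runif(40, 0.1, 2)
    expect_lt(max(abs(whittaker_smooth(y, w, 10) -
                        dense_whittaker(y, w, 10))), 1e-8)
  }
  # and across magnitudes of lambda
  y <- cumsum(rnorm(60))
  w <- rep(1, 60)
  for (lam in c(1, 1e3, 1e6)) {
    expect_lt(max(abs(whittaker_smooth(y, w, lam) -
                        dense_whittaker(y, w, lam))), 1e-8)
  }
})

test_that("whittaker input validation", {
  expect_error(whittaker_smooth(1:10, rep(0, 10), 1), "positive weights")
  expect_error(whittaker_smooth(c(1, NA, 3, 4), rep(1, 4), 1), "finite")
  expect_error(whittaker_smooth(1:10, rep(1, 10), -1), "lambda")
})

test_that("airpls flattens a pure smooth background", {
  x <- seq(-1, 1, length.out = 80)
  y <- 10 + 3 * x + 2 * x^2
  r <- airpls(y)
  expect_true(r$converged)
  expect_lt(sum(abs(r$corrected)) / sum(abs(y)), 0.01)
  expect_equal(r$corrected + r$baseline, y, tolerance = 1e-12)
})

test_that("airpls recovers a known band area on a curved background", {
  # band on the generator's default background shape; the narrow marker
  # window keeps residual-baseline bias out of the integral
  ax <- axis_standard()
  x <- seq(-1, 1, length.out = 80)
  bg <- 10 * (1 + 0.1 * x - 0.1 * x^2)
  band <- band_spectrum(center = 733, fwhm = 10, amp = 5)$intensity
  idx <- pesrs:::window_channels(ax, c(715, 745))
  dx <- mean(diff(ax$wavenumbers))
  true_area <- sum(band[idx]) * dx
  for (lam in c(1e3, 3e3)) {
    r <- airpls(bg + band, lambda = lam)
    got <- sum(r$corrected[idx]) * dx
    expect_lt(abs(got - true_area) / true_area, 0.10)
  }
  # low lambda clips band wings into the baseline: a known trade-off,
  # bounded but not free
  r_lo <- airpls(bg + band, lambda = 1e2)
  expect_lt(abs(sum(r_lo$corrected[idx]) * dx - true_area) / true_area,
            0.25)
})

test_that("off-resonance spectra reduce to a featureless baseline", {
  # no band inside the window: background + noise only
  set.seed(7)
  sigma <- 0.1
  x <- seq(-1, 1, length.out = 80)
  y <- 15 * (1 + 0.1 * x - 0.05 * x^2) + rnorm(80, 0, sigma)
  r <- airpls(y)
  expect_lt(max(r$corrected), 5 * sigma)
})

test_that("airpls weights vanish where the residual is non-negative", {
  set.seed(3)
  y <- 10 + cumsum(rnorm(80, 0, 0.3)) +
    band_spectrum(center = 700, fwhm = 12, amp = 4)$intensity
  r <- airpls(y)
  d <- y - r$baseline
  inner <- 2:79
  expect_true(all(r$weights[inner][d[inner] >= 0] == 0))
  expect_true(all(r$weights[inner][d[inner] < 0] > 0))
})

test_that("penalty is monotone in lambda and airpls is idempotent", {
  set.seed(9)
  y <- rnorm(60) + 5
  w <- rep(1, 60)
  pen <- vapply(c(1, 10, 100, 1e3, 1e4), function(l) {
    z <- whittaker_smooth(y, w, l)
    sum(diff(z, differences = 2)^2)
  }, numeric(1))
  expect_true(all(diff(pen) <= 1e-12))
  # a returned baseline is its own baseline
  ax <- axis_standard()
  x <- seq(-1, 1, length.out = 80)
  set.seed(9)
  spec <- 10 * (1 + 0.1 * x - 0.1 * x^2) +
    5 * band_spectrum(center = 733)$intensity + rnorm(80, 0, 0.1)
  r <- airpls(spec)
  r2 <- airpls(r$baseline)
  expect_lt(sum(abs(r2$corrected)), 0.001 * sum(abs(r$baseline)))
})

test_that("no band structure is invented from featureless noisy input", {
  # airPLS hugs the lower noise envelope (a uniform positive offset on
  # pure noise); the scientific requirement is that it adds no localized
  # structure in the marker window
  set.seed(5)
  ax <- axis_standard()
  idx <- pesrs:::window_channels(ax, c(715, 745))
  flank <- c(pesrs:::window_channels(ax, c(685, 714)),
             pesrs:::window_channels(ax, c(746, 775)))
  n_rep <- 40
  d <- vapply(seq_len(n_rep), function(i) {
    corr <- airpls(10 + rnorm(80))$corrected
    mean(corr[idx]) - mean(corr[flank])
  }, numeric(1))
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(n_rep))
  # and the corrected spectrum stays within the noise scale
  set.seed(6)
  corr <- airpls(10 + rnorm(80))$corrected
  expect_lt(max(corr), 5)
})

test_that("cube baseline subtraction is exact, deterministic, and flags pixels", {
  cube <- background_cube(seed = 2L, sigma = 0.1)
  r <- subtract_baseline_cube(cube)
  expect_lt(max(abs(r$corrected$data + r$baseline$data - cube$data)), 1e-10)
  # residual fluctuation at the noise scale; the envelope-hugging offset
  # of the estimator adds a uniform positive shift bounded by ~2 sigma
  cc <- r$corrected$data
  centered <- cc - rep(apply(cc, c(1, 2), mean), dim(cc)[3])
  expect_lt(sqrt(mean(centered^2)), 1.5 * 0.1)
  expect_lt(sqrt(mean(cc^2)), 3 * 0.1)

  # identical spectra give identical per-pixel results
  y <- 10 + band_spectrum(center = 733, amp = 1)$intensity
  same <- hyper_cube(array(rep(y, each = 16), dim = c(4, 4, 80)),
                     axis_standard())
  rs <- subtract_baseline_cube(same)
  expect_equal(length(unique(as.numeric(rs$iterations))), 1L)
  expect_lt(max(apply(cube_matrix(rs$corrected), 2, function(col)
    diff(range(col)))), 1e-10)
})
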