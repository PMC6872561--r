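test_that("fano model: center value, Lorentzian limit, antiresonance", {
  nu <- seq(680, 780, by = 0.5)
  expect_equal(fano_model(733, 733, 10, 8, 0.2, 1), 0.2 * 64 + 1)
  # q -> Inf with A q^2 fixed tends to a Lorentzian of FWHM Gamma
  q <- 1e6
  h <- 2
  fano <- fano_model(nu, 733, 10, q, h / q^2, 0)
  lor <- h / (1 + ((nu - 733) / 5)^2)
  expect_lt(max(abs(fano - lor)), 1e-5 * h)
  # q = 0: symmetric dip reaching c at the center
  dip <- fano_model(nu, 733, 10, 0, 1, 0.3)
  expect_equal(dip[nu == 733], 0.3)
  expect_true(all(dip >= 0.3 - 1e-12))
  expect_error(fano_model(nu, 733, -1, 8, 1, 0), "gamma")
})

test_that("noiseless Fano parameters are recovered within 1%", {
  ax <- axis_highres()
  truth <- list(nu0 = 733, gamma = 10, q = 8, A = 0.05, c = 0.2)
  y <- fano_model(ax$wavenumbers, truth$nu0, truth$gamma, truth$q,
                  truth$A, truth$c)
  f <- fit_fano(spectrum(y, ax))
  expect_true(f$success)
  expect_lt(abs(f$center - truth$nu0) / truth$nu0, 0.01)
  expect_lt(abs(f$gamma - truth$gamma) / truth$gamma, 0.01)
  expect_lt(abs(f$q - truth$q) / abs(truth$q), 0.01)
})

test_that("fit is a fixed point across a parameter grid and scale-equivariant", {
  ax <- axis_highres()
  for (gam in c(6, 10, 20)) {
    for (q in c(-20, 5, 200)) {
      y <- fano_model(ax$wavenumbers, 730, gam, q, 1 / q^2, 0.1)
      f <- fit_fano(spectrum(y, ax))
      expect_true(f$success)
      expect_lt(abs(f$gamma - gam) / gam, 0.02)
      expect_lt(abs(f$center - 730), 1)
    }
  }
  y <- fano_model(ax$wavenumbers, 733, 12, 30, 1e-3, 0.05)
  f1 <- fit_fano(spectrum(y, ax))
  f5 <- fit_fano(spectrum(5 * y, ax))
  expect_equal(f5$amplitude / f1$amplitude, 5, tolerance = 1e-3)
  expect_equal(f5$offset / f1$offset, 5, tolerance = 1e-3)
  expect_equal(f5$gamma, f1$gamma, tolerance = 1e-4)
  expect_equal(f5$center, f1$center, tolerance = 1e-6)
})

test_that("median fitted width of noisy Lorentzian bands lies in [9, 11]", {
  set.seed(8)
  ax <- axis_highres()
  clean <- fano_model(ax$wavenumbers, 733, 10, 1e3, 1 / 1e6, 0)
  peak <- max(clean)
  gammas <- vapply(1:200, function(i) {
    y <- clean + rnorm(length(clean), 0, peak / 30)
    f <- fit_fano(spectrum(y, ax))
    if (f$success) f$gamma else NA_real_
  }, numeric(1))
  expect_gt(mean(!is.na(gammas)), 0.9)
  med <- median(gammas, na.rm = TRUE)
  expect_gte(med, 9); expect_lte(med, 11)
})

test_that("flat spectra fail gracefully", {
  f <- fit_fano(spectrum(rep(1, 80), axis_standard()))
  expect_false(f$success)
  expect_error(fit_fano(spectrum(rep(1, 80), axis_standard()),
                        window = c(100, 200)), "window")
})

test_that("mixture events fit broader than single-molecule events", {
  ax <- axis_highres()
  s14 <- band_profile(ax$wavenumbers, species_band("14NA", 733))
  s15 <- band_profile(ax$wavenumbers, species_band("15NA", 726))
  set.seed(9)
  fit_g <- function(y) {
    f <- fit_fano(spectrum(y + rnorm(length(y), 0, 0.02), ax))
    if (f$success) f$gamma else NA_real_
  }
  g_sm <- vapply(1:40, function(i) fit_g(runif(1, 0.8, 1.2) * s14),
                 numeric(1))
  g_mix <- vapply(1:40, function(i)
    fit_g(runif(1, 0.4, 0.6) * s14 + runif(1, 0.4, 0.6) * s15), numeric(1))
  expect_gt(median(g_mix, na.rm = TRUE), median(g_sm, na.rm = TRUE))
  expect_lt(abs(median(g_sm, na.rm = TRUE) - 10), 1)
})

test_that("peak-area maps conserve molecular mass and scale linearly", {
  cfg <- pipeline_config(scene = list(grid = c(32L, 32L), n_aggregates = 1L,
                                      aggregate_radius_um = c(0.3, 0.8),
                                      hotspots_per_aggregate = 2,
                                      mu = 1, f14 = 1,
                                      background_floor = 0,
                                      background_amplitude = 0))
  sc <- generate_scene(cfg)
  sc$hotspots <- data.frame(row = 16L, col = 16L, aggregate = 1L, g = 1)
  sc$molecules <- data.frame(hotspot = 1L, species = "14NA", eta = 2)
  ax <- axis_standard()
  cube <- render_cube(sc, ax, noise_sigma = 0)
  area <- peak_area_map(cube, window = c(700, 766))
  idx <- pesrs:::window_channels(ax, c(700, 766))
  wn <- ax$wavenumbers[idx]
  prof <- sc$params$signal_scale * 2 * band_profile(wn, sc$bands[["14NA"]])
  m_true <- sum(diff(wn) * (head(prof, -1) + tail(prof, -1)) / 2)
  expect_equal(sum(area), m_true, tolerance = 1e-8)
  # doubling the weight doubles the area
  sc$molecules$eta <- 4
  area2 <- peak_area_map(render_cube(sc, ax, noise_sigma = 0),
                         window = c(700, 766))
  expect_equal(sum(area2), 2 * sum(area), tolerance = 1e-8)
  # background-only cube: mean area consistent with zero
  set.seed(10)
  noise <- hyper_cube(array(rnorm(32 * 32 * 80, 0, 0.1),
                            dim = c(32, 32, 80)), ax)
  a <- peak_area_map(noise)
  expect_lt(abs(mean(a)), 3 * sd(a) / sqrt(length(a)))
})

test_that("snr matches its definition and guards degenerate noise", {
  ax <- axis_standard()
  set.seed(11)
  # pure noise: SNR near the expected max of |window| Gaussians over sd
  n_rep <- 200
  vals <- vapply(seq_len(n_rep), function(i)
    snr(spectrum(rnorm(80), ax)), numeric(1))
  k <- length(pesrs:::window_channels(ax, c(715, 745)))
  sim <- vapply(seq_len(2000), function(i) max(rnorm(k)), numeric(1))
  expect_lt(abs(mean(vals) - mean(sim)), 4 * sd(sim) / sqrt(n_rep) + 0.2)
  # 33-sigma peak reads back as SNR ~ 33
  y <- rnorm(80)
  i733 <- which.min(abs(ax$wavenumbers - 733))
  y[i733] <- y[i733] + 33
  got <- snr(spectrum(y, ax))
  expect_gt(got, 33 * 0.7); expect_lt(got, 33 * 1.5)
  # capped sentinel for vanishing noise, hard errors for degenerate input
  y <- rep(0, 80)
  y[5] <- 1e-150        # noise window sd collapses toward zero
  y[i733] <- 5
  expect_equal(snr(spectrum(y, ax)), 1e9)
  expect_error(snr(spectrum(rep(0, 80), ax)), "zero-variance")
  expect_error(snr(spectrum(rnorm(80), ax), signal_window = c(700, 760),
                   noise_window = c(720, 740)), "disjoint")
})
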