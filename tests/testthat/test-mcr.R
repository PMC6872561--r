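test_that("exact factorizations are a fixed point of MCR-ALS", {
  set.seed(1)
  S_true <- rbind(band_spectrum(733, amp = 1)$intensity,
                  band_spectrum(726, amp = 1)$intensity)
  S_true <- S_true / apply(S_true, 1, max)  # the scale convention of S
  C_true <- matrix(rexp(200 * 2), 200, 2)
  D <- C_true %*% S_true
  r <- mcr_als(D, S_true)
  expect_lt(max(abs(r$C - C_true)) / max(C_true), 1e-6)
  expect_lt(tail(r$lof_trace, 1), 1e-4)
  expect_true(all(r$C >= 0))
  expect_true(all(r$S >= 0))
  expect_equal(unname(apply(r$S, 1, max)), c(1, 1))
})

test_that("small-k NNLS matches the reference active-set solver", {
  set.seed(2)
  for (k in c(1L, 2L, 3L)) {
    A <- matrix(rnorm(12 * k), 12, k)
    D <- matrix(rnorm(30 * 12), 30, 12)
    mine <- pesrs:::nnls_rows(D, A)
    ref <- t(apply(D, 1, function(d) pracma::lsqnonneg(A, d)$x))
    ref <- matrix(ref, nrow = 30, ncol = k)
    expect_lt(max(abs(mine - ref)), 1e-8)
  }
})

test_that("one-component unmixing equals the clipped projection", {
  set.seed(3)
  s <- band_spectrum(733, amp = 1)$intensity
  D <- matrix(rnorm(50 * 80, sd = 0.2), 50, 80) + outer(rnorm(50), s)
  C <- pesrs:::nnls_rows(D, cbind(s))
  expect_equal(as.numeric(C), as.numeric(pmax(D %*% s / sum(s^2), 0)),
               tolerance = 1e-10)
})

test_that("objective is non-increasing and CS is invariant to normalization", {
  set.seed(4)
  S_true <- rbind(band_spectrum(733)$intensity,
                  band_spectrum(726)$intensity)
  D <- matrix(rexp(300 * 2), 300, 2) %*% S_true +
    abs(matrix(rnorm(300 * 80, sd = 0.05), 300, 80))
  S0 <- S_true + abs(matrix(rnorm(160, sd = 0.02), 2, 80))
  r <- mcr_als(D, S0, max_iter = 20L)
  expect_true(all(diff(r$lof_trace) <= 1e-9))
  # renormalized (C, S) reproduce the same fit as any rescaling
  fit <- r$C %*% r$S
  sc <- c(2, 0.5)
  fit2 <- (r$C %*% diag(1 / sc)) %*% (diag(sc) %*% r$S)
  expect_lt(max(abs(fit - fit2)), 1e-10)
})

test_that("checkerboard scene unmixes into its two species", {
  set.seed(5)
  ax <- axis_standard()
  s14 <- band_spectrum(733)$intensity
  s15 <- band_spectrum(726)$intensity
  data <- array(0, dim = c(20, 20, 80))
  amp <- matrix(runif(400, 0.5, 2), 20, 20)
  for (i in 1:20) for (j in 1:20) {
    pure <- if (j <= 10) s14 else s15
    data[i, j, ] <- amp[i, j] * pure + rnorm(80, 0, 0.02)
  }
  cube <- hyper_cube(data, ax)
  um <- unmix_cube(cube, rbind(s14, s15))
  dominant14 <- um$maps[[1]] > um$maps[[2]]
  expect_gt(mean(dominant14[, 1:10]), 0.99)
  expect_gt(mean(!dominant14[, 11:20]), 0.99)
})

test_that("noisy bianalyte cube recovers per-species signal mass (r >= 0.95)", {
  cfg <- pipeline_config(seed = 31L,
                         scene = list(grid = c(48L, 48L), n_aggregates = 3L,
                                      hotspots_per_aggregate = 6,
                                      mu = 2, f14 = 0.5,
                                      species_variant = "single"))
  sc <- generate_scene(cfg)
  ax <- axis_highres()
  noisy <- render_cube(sc, ax, noise_sigma = 0.05)
  bg <- render_background(sc, ax)
  corr <- hyper_cube(noisy$data - bg$data, ax)
  S0 <- rbind(band_profile(ax$wavenumbers, sc$bands[["14NA"]]),
              band_profile(ax$wavenumbers, sc$bands[["15NA"]]))
  um <- unmix_cube(corr, S0)
  # per-pixel true signal mass per species: noise-free render of each
  # species alone (PSF included), channel-summed
  species_mass <- function(keep) {
    sub <- sc
    sub$molecules <- sc$molecules[sc$molecules$species == keep, ,
                                  drop = FALSE]
    apply(render_cube(sub, ax, noise_sigma = 0)$data - bg$data,
          c(1, 2), sum)
  }
  t14 <- species_mass("14NA"); t15 <- species_mass("15NA")
  lit <- t14 + t15 > 0.05 * max(t14 + t15)
  expect_gte(cor(c(t14[lit], t15[lit]),
                 c(um$maps[[1]][lit], um$maps[[2]][lit])), 0.95)
})

test_that("background-only cubes yield near-zero concentrations", {
  ax <- axis_highres()
  cube <- render_cube(generate_scene(pipeline_config(
    seed = 6L, scene = list(grid = c(32L, 32L), n_aggregates = 2L, mu = 0,
                            aggregate_radius_um = c(0.3, 0.8),
                            noise_sigma = 0.05))), ax)
  bl <- subtract_baseline_cube(cube)
  S0 <- rbind(band_spectrum(733, axis = ax)$intensity,
              band_spectrum(724, axis = ax)$intensity)
  um <- unmix_cube(bl$corrected, S0)
  # "sigma-equivalent" scale: the corrected cube's own residual SD
  expect_lt(sqrt(mean(um$maps[[1]]^2 + um$maps[[2]]^2)),
            2 * sd(bl$corrected$data))
})

test_that("permuting S0 rows permutes the concentration maps", {
  set.seed(7)
  S0 <- rbind(band_spectrum(733)$intensity, band_spectrum(726)$intensity)
  D <- matrix(rexp(100 * 2), 100, 2) %*% S0
  r1 <- mcr_als(D, S0)
  r2 <- mcr_als(D, S0[2:1, ])
  expect_lt(max(abs(r1$C - r2$C[, 2:1])), 1e-8)
})

test_that("degenerate initializations are flagged", {
  s <- band_spectrum(733)$intensity
  D <- matrix(rexp(50), 50, 1) %*% rbind(s)
  expect_warning(mcr_als(D, rbind(s, s), max_iter = 3L), "rank-deficient")
  # negative data draw the fit to zero: both the input check and the
  # vanished-component flag fire
  expect_warning(
    expect_warning(mcr_als(-D, rbind(s), max_iter = 2L),
                   "negative-dominated"),
    "vanished")
})

test_that("reference spectra come from the brightest pixels, normalized", {
  sc <- generate_scene(small_config(seed = 13L, mu = 3, f14 = 1))
  ax <- axis_standard()
  cube <- render_cube(sc, ax, noise_sigma = 0.02)
  bg <- render_background(sc, ax)
  corr <- hyper_cube(cube$data - bg$data, ax)
  S0 <- build_reference_spectra(list(`14NA` = corr))
  expect_equal(max(S0), 1)
  expect_true(all(S0 >= 0))
  peak_wn <- ax$wavenumbers[which.max(S0[1, ])]
  expect_lt(abs(peak_wn - 733), mean(diff(ax$wavenumbers)))
  # single noiseless spectrum: S0 is that spectrum normalized
  y <- band_spectrum(726, amp = 3)$intensity
  one <- hyper_cube(array(y, dim = c(1, 1, 80)), ax)
  expect_equal(as.numeric(build_reference_spectra(list(one))),
               y / max(y), tolerance = 1e-12)
  # all-zero reference refused
  zero <- hyper_cube(array(0, dim = c(2, 2, 80)), ax)
  expect_error(build_reference_spectra(list(zero)), "noise floor")
})
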