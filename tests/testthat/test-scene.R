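test_that("degenerate occupancy and species fractions behave as stated", {
  cfg <- pipeline_config(scene = list(grid = c(48L, 48L), n_aggregates = 2L,
                                      mu = 0))
  sc <- generate_scene(cfg)
  expect_equal(nrow(sc$molecules), 0L)
  cube <- render_cube(sc, axis_standard(), noise_sigma = 0)
  bg <- render_background(sc, axis_standard())
  expect_cube_equal(cube, bg, tol = 1e-12)

  sc1 <- generate_scene(small_config(mu = 1, f14 = 1))
  expect_true(all(sc1$molecules$species == "14NA"))
  sc0 <- generate_scene(small_config(mu = 1, f14 = 0))
  expect_true(all(sc0$molecules$species == "15NA"))
})

test_that("hot-spot occupancy follows Poisson(mu)", {
  # fraction occupied at mu = 0.5 vs the closed form 1 - exp(-0.5),
  # and a chi-square goodness-of-fit on the full count distribution
  cfg <- pipeline_config(seed = 11L,
                         scene = list(grid = c(200L, 200L),
                                      n_aggregates = 40L,
                                      hotspots_per_aggregate = 250,
                                      mu = 0.5))
  sc <- generate_scene(cfg)
  H <- nrow(sc$hotspots)
  expect_gt(H, 5000)
  counts <- tabulate(sc$molecules$hotspot, nbins = H)
  p_occ <- 1 - exp(-0.5)
  se <- sqrt(p_occ * (1 - p_occ) / H)
  expect_lt(abs(mean(counts > 0) - p_occ), 3 * se)

  kmax <- max(counts)
  obs <- tabulate(counts + 1L, nbins = kmax + 1L)
  prob <- dpois(0:kmax, 0.5)
  prob[kmax + 1L] <- 1 - sum(prob[seq_len(kmax)])
  keep <- prob * H >= 5
  chi <- sum((obs[keep] - H * prob[keep])^2 / (H * prob[keep]))
  expect_gt(pchisq(chi, df = sum(keep) - 1L, lower.tail = FALSE), 0.01)
})

test_that("rendered signal is linear in pump power", {
  sc <- generate_scene(small_config(seed = 4L))
  ax <- axis_standard()
  bg <- render_background(sc, ax)$data
  c1 <- render_cube(sc, ax, noise_sigma = 0)$data - bg
  c2 <- render_cube(sc, ax, noise_sigma = 0,
                    power_pump_mw = 2 * sc$params$power_pump_mw)$data - bg
  expect_lt(max(abs(c2 - 2 * c1)), 1e-10 * max(abs(c1)))
})

test_that("an isolated molecule reproduces the closed-form band value", {
  cfg <- pipeline_config(scene = list(grid = c(32L, 32L), n_aggregates = 1L,
                                      aggregate_radius_um = c(0.3, 0.8),
                                      hotspots_per_aggregate = 1,
                                      mu = 1, f14 = 1, psf_fwhm_nm = 0))
  sc <- generate_scene(cfg)
  # overwrite the random draws with known values
  sc$hotspots <- data.frame(row = 16L, col = 16L, aggregate = 1L, g = 2)
  sc$molecules <- data.frame(hotspot = 1L, species = "14NA", eta = 1.5)
  ax <- axis_standard()
  cube <- render_cube(sc, ax, noise_sigma = 0)
  bg <- render_background(sc, ax)
  sig <- cube$data[16, 16, ] - bg$data[16, 16, ]
  expected <- sc$params$signal_scale * 2 * 1.5 *
    band_profile(ax$wavenumbers, sc$bands[["14NA"]])
  expect_lt(max(abs(sig - expected)), 1e-8)
})

test_that("integrated signal is conserved under the PSF", {
  sc <- generate_scene(small_config(seed = 8L, mu = 2))
  ax <- axis_standard()
  cube <- render_cube(sc, ax, noise_sigma = 0)
  bg <- render_background(sc, ax)
  total <- sum(cube$data - bg$data)
  per_mol <- vapply(seq_len(nrow(sc$molecules)), function(m) {
    h <- sc$molecules$hotspot[m]
    sc$params$signal_scale * sc$hotspots$g[h] * sc$molecules$eta[m] *
      sum(band_profile(ax$wavenumbers, sc$bands[[sc$molecules$species[m]]]))
  }, numeric(1))
  expect_equal(total, sum(per_mol), tolerance = 1e-8)
})

test_that("same config and seed give bit-identical scene and cube", {
  cfg <- small_config(seed = 21L)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$molecules, s2$molecules)
  expect_identical(s1$hotspots, s2$hotspots)
  expect_identical(render_cube(s1, axis_standard())$data,
                   render_cube(s2, axis_standard())$data)
})

test_that("time-lapse dynamics: stable, forced bleach, telegraph stationarity", {
  sc <- generate_scene(small_config(seed = 5L, mu = 1, noise_sigma = 0))
  ax <- axis_standard()
  stable <- dynamics_params(blink_on = 0, blink_off = 0, bleach_prob = 0,
                            stable_fraction = 1)
  tl <- render_timelapse(sc, ax, n_frames = 3L, dynamics = stable, seed = 2L)
  expect_cube_equal(tl$frames[[1]], tl$frames[[2]], tol = 1e-12)
  expect_cube_equal(tl$frames[[1]], tl$frames[[3]], tol = 1e-12)
  expect_true(all(tl$states))

  bleach <- dynamics_params(blink_on = 0, blink_off = 0, bleach_prob = 1,
                            stable_fraction = 0)
  tb <- render_timelapse(sc, ax, n_frames = 4L, dynamics = bleach, seed = 2L)
  expect_true(all(tb$states[, 1]))
  expect_false(any(tb$states[, -1]))

  # stationary two-state chain: fraction on ~ 0.5 at rates (0.2, 0.2)
  scL <- generate_scene(pipeline_config(
    seed = 6L, scene = list(grid = c(120L, 120L), n_aggregates = 10L,
                            hotspots_per_aggregate = 40, mu = 1)))
  tel <- dynamics_params(blink_on = 0.2, blink_off = 0.2, bleach_prob = 0,
                         stable_fraction = 0)
  n_frames <- max(3L, ceiling(1e4 / nrow(scL$molecules)))
  states <- pesrs:::timelapse_states(scL, n_frames, tel, seed = 3L)
  n_mf <- length(states)
  se <- sqrt(0.25 / n_mf)
  expect_lt(abs(mean(states) - 0.5), 3 * se)
})

test_that("scene validation rejects impossible parameters", {
  expect_error(pipeline_config(scene = list(mu = -1)), "mu")
  expect_error(generate_scene(pipeline_config(
    scene = list(grid = c(8L, 8L)))), "grid too small")
})
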