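# Small scenes and cubes shared across tests. Grids are kept small so the
# suite stays fast; the generator itself is exercised at full acquisition
# size in the acceptance tests.

small_config <- function(seed = 1L, ...) {
  pipeline_config(seed = seed,
                  scene = merge_small(list(grid = c(48L, 48L),
                                           n_aggregates = 2L,
                                           hotspots_per_aggregate = 4,
                                           mu = 2, f14 = 1), list(...)))
}

merge_small <- function(base, override) {
  for (n in names(override)) base[[n]] <- override[[n]]
  base
}

# A cube holding pure background plus optional noise, no molecules.
# Aggregate radii are shrunk so the placement margin fits small grids.
background_cube <- function(seed = 1L, sigma = 0, grid = c(32L, 32L)) {
  cfg <- pipeline_config(seed = seed,
                         scene = list(grid = grid, n_aggregates = 2L, mu = 0,
                                      aggregate_radius_um = c(0.3, 0.8),
                                      noise_sigma = sigma))
  sc <- generate_scene(cfg)
  render_cube(sc, axis_standard())
}

# Deterministic single-band spectrum on the standard axis.
band_spectrum <- function(center = 733, fwhm = 10, amp = 1, q = 1000,
                          offset = 0, axis = axis_standard()) {
  b <- species_band("x", center, fwhm = fwhm, q = q)
  spectrum(amp * band_profile(axis$wavenumbers, b) + offset, axis)
}

expect_cube_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a$data - b$data)), tol)
  expect_true(axis_equal(a$axis, b$axis))
}
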