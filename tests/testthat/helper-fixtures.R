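# Shared fixtures for the test suite. Everything is generated in code;
# heavier shared objects are built once per session and cached.

fixture_env <- new.env(parent = emptyenv())

# small sphere-corrected lookup table shared by the lighter tests
fixture_small_lut <- function() {
  if (is.null(fixture_env$small_lut)) {
    fixture_env$small_lut <- build_lut(
      mua_grid = log_mua_grid(1e-3, 0.5, 8),
      musp_grid = seq(0.5, 8, length.out = 8),
      fixed_params = list(g = 0.75, n = 1.41, d = 2),
      sphere = sphere_geometry(), n_photons = 2e4, seed = 101)
  }
  fixture_env$small_lut
}

# noise-free synthetic dataset over a compact wavelength range, driven by
# the shared lookup table as forward engine
fixture_dataset <- function(pl_yield = 0.2, shot_noise = FALSE, seed = 5,
                            dye_concentration = 4) {
  phantom <- phantom_truth(musp_600 = 4, dye_concentration = dye_concentration,
                           pl_yield = pl_yield, thickness_d = 2)
  generate_channels(
    phantom, sphere = sphere_geometry(),
    noise = noise_model(shot_noise = shot_noise, seed = seed),
    engine = fixture_small_lut(),
    excitation_grid = seq(440, 680, by = 10))
}
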