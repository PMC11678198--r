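# Synthetic phantom generator: truth spectra, the constructed-inverse
# identity with the processing pipeline, and photoluminescence behaviour.

test_that("truth spectra follow the power law and the linear dye band", {
  flat <- phantom_truth(musp_600 = 3, scatter_power_b = 0)
  ts <- truth_spectra(flat, seq(400, 900, by = 100))
  expect_true(all(ts$mu_s_prime == 3))
  c0 <- phantom_truth(dye_concentration = 0)
  ts0 <- truth_spectra(c0, seq(400, 900, by = 100))
  expect_true(all(ts0$mu_a == c0$baseline_mua))
  # peak absorption scales as the printed concentration series
  concs <- c(2.66, 4, 5.33, 6.66)
  peaks <- vapply(concs, function(cc) {
    ph <- phantom_truth(dye_concentration = cc)
    max(truth_spectra(ph, seq(450, 650, by = 1))$mu_a - ph$baseline_mua)
  }, numeric(1))
  expect_equal(peaks / peaks[2], concs / concs[2], tolerance = 1e-9)
  # power law pivots at 600 nm
  ph <- phantom_truth(musp_600 = 4, scatter_power_b = 1.3)
  ts2 <- truth_spectra(ph, c(300, 600, 1200))
  expect_equal(ts2$mu_s_prime[2], 4)
  expect_equal(ts2$mu_s_prime[1], 4 * (300 / 600)^(-1.3))
})

test_that("noise-free channels are an exact constructed inverse of the calibration algebra", {
  ds <- fixture_dataset(pl_yield = 0, shot_noise = FALSE)
  rt <- compute_rt(signal_set(ds$scans, ds$rho_cal))
  lut <- fixture_small_lut()
  expected <- t(vapply(seq_len(nrow(ds$truth)), function(k) {
    ip <- lumisphere:::lut_interp(lut, ds$truth$mu_a[k],
                                  ds$truth$mu_s_prime[k])
    c(ip$R, ip$T)
  }, numeric(2)))
  expect_equal(rt$R, expected[, 1], tolerance = 1e-12)
  expect_equal(rt$T, expected[, 2], tolerance = 1e-12)
})

test_that("without photoluminescence the mono- and polychromatic analyses coincide", {
  ds <- fixture_dataset(pl_yield = 0, shot_noise = FALSE)
  mono <- compute_rt(signal_set(ds$scans, ds$rho_cal))
  poly <- compute_rt_polychromatic(ds$scans, ds$rho_cal)
  expect_equal(poly$R, mono$R, tolerance = 1e-6)
  expect_equal(poly$T, mono$T, tolerance = 1e-6)
})

test_that("photoluminescence leaves the monochromatic analysis untouched but contaminates the broadband one", {
  ds0 <- fixture_dataset(pl_yield = 0, shot_noise = FALSE)
  ds1 <- fixture_dataset(pl_yield = 0.2, shot_noise = FALSE)
  mono0 <- compute_rt(signal_set(ds0$scans, ds0$rho_cal))
  mono1 <- compute_rt(signal_set(ds1$scans, ds1$rho_cal))
  expect_equal(mono1$R, mono0$R, tolerance = 1e-10)
  expect_equal(mono1$T, mono0$T, tolerance = 1e-10)

  poly1 <- compute_rt_polychromatic(ds1$scans, ds1$rho_cal)
  band <- mono1$wavelength >= 540 & mono1$wavelength <= 580
  expect_true(all(poly1$R[band] > mono1$R[band]))
  expect_true(all(poly1$T[band] > mono1$T[band]))
  # doubling the emission amplitude grows the artifact monotonically
  ds2 <- fixture_dataset(pl_yield = 0.4, shot_noise = FALSE)
  poly2 <- compute_rt_polychromatic(ds2$scans, ds2$rho_cal)
  expect_true(all(poly2$R[band] > poly1$R[band]))
})

test_that("the emission scan shows the Stokes-shifted band only under dye excitation", {
  ds <- fixture_dataset(pl_yield = 0.2, shot_noise = FALSE)
  srb <- preprocess(ds$scans$SRB)
  pl_exc <- extract_pl(srb, 520)
  peak_bin <- which.max(ifelse(is.na(pl_exc$rate), -Inf, pl_exc$rate))
  expect_equal(pl_exc$emission_nm[peak_bin], 548)
  # excitation far beyond the dye band: no emission outside the elastic peak
  pl_900 <- extract_pl(srb, 660)
  expect_lt(max(pl_900$rate, na.rm = TRUE),
            1e-6 * max(pl_exc$rate, na.rm = TRUE))
  # dye-free sample: photoluminescence consistent with zero
  ds0 <- fixture_dataset(pl_yield = 0.2, shot_noise = FALSE,
                         dye_concentration = 0)
  pl_c0 <- extract_pl(preprocess(ds0$scans$SRB), 520)
  expect_lt(max(pl_c0$rate, na.rm = TRUE),
            1e-9 * max(pl_exc$rate, na.rm = TRUE))
})

test_that("shot noise scales with the inverse square root of the acquisition time", {
  phantom <- phantom_truth(musp_600 = 4, dye_concentration = 0, pl_yield = 0)
  lut <- fixture_small_lut()
  exc <- seq(450, 650, by = 10)
  run <- function(scale, seed) {
    ds <- generate_channels(phantom, noise = noise_model(shot_noise = TRUE,
                                                         seed = seed),
                            engine = lut, excitation_grid = exc,
                            lamp_scale = 1e4, n_averages = 10 * scale)
    rt <- compute_rt(signal_set(ds$scans, ds$rho_cal))
    rt$R
  }
  # quadrupling the total integration time halves the shot-noise spread of
  # the recovered reflectance
  r1 <- unlist(lapply(1:4, function(s) run(1, 100 + s)))
  r4 <- unlist(lapply(1:4, function(s) run(4, 200 + s)))
  mono0 <- generate_channels(phantom,
                             noise = noise_model(shot_noise = FALSE, seed = 1),
                             engine = lut, excitation_grid = exc)
  r0 <- compute_rt(signal_set(mono0$scans, mono0$rho_cal))$R
  sd1 <- sd(r1 - rep(r0, 4)); sd4 <- sd(r4 - rep(r0, 4))
  expect_equal(sd1 / sd4, 2, tolerance = 0.35)
})

test_that("the sample matrix spans concentrations x particle levels with c0 included", {
  batch <- matrix_of_samples()
  expect_length(batch, 5 * 3) # four concentrations + c0, three loadings
  concs <- vapply(batch, function(p) p$dye_concentration, numeric(1))
  musps <- vapply(batch, function(p) p$musp_600, numeric(1))
  expect_setequal(unique(concs), c(0, 2.66, 4, 5.33, 6.66))
  expect_setequal(unique(musps), c(2, 4, 6))
  for (p in batch) expect_s3_class(p, "phantom_truth")
  single <- matrix_of_samples(4, 2, 2)
  expect_length(single, 2) # c0 is always added
  expect_error(matrix_of_samples(numeric(0), 2, 2), "concentrations")
})

test_that("phantom invariants are enforced", {
  expect_error(phantom_truth(pl_peak_nm = 500), "pl_peak_nm")
  expect_error(phantom_truth(musp_600 = -1), "musp_600")
  expect_error(phantom_truth(pl_yield = 1.5), "pl_yield")
})
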