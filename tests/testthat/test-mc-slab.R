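# Monte Carlo slab solver: closed-form limits, conservation, sampling
# primitives and reproducibility.

test_that("non-scattering non-absorbing n = 1.5 slab reproduces the Fresnel multiple-reflection sum", {
  # R = 2 r / (1 + r), T = 1 - R with r = ((n-1)/(n+1))^2
  r <- 0.04
  props <- optical_properties(0, 0, g = 0.75, n_sample = 1.5, thickness_d = 2)
  res <- simulate_rt(props, pencil_beam(), n_photons = 1e6, seed = 42)
  expect_lt(abs(res$R_total - 2 * r / (1 + r)), 3 * res$se_R)
  expect_lt(abs(res$T_total - (1 - 2 * r / (1 + r))), 3 * res$se_T)
})

test_that("index-matched absorbing-only slab follows Beer-Lambert", {
  props <- optical_properties(0.1, 0, g = 0, n_sample = 1, thickness_d = 4)
  res <- simulate_rt(props, pencil_beam(), n_photons = 1e6, seed = 7)
  expect_lt(abs(res$T_total - exp(-0.4)), 3 * res$se_T)
  expect_identical(res$R_total, 0)
})

test_that("tallies conserve the launched weight to bookkeeping precision", {
  cases <- list(
    c(0, 0, 0.75, 1.5, 2), c(0.1, 0, 0, 1, 4), c(0.02, 4, 0.75, 1.41, 2),
    c(0.5, 1, 0.9, 1.33, 1), c(0, 6, 0.75, 1.41, 2), c(1, 0.1, -0.5, 1.2, 3))
  for (cs in cases) {
    props <- optical_properties(cs[1], cs[2], g = cs[3], n_sample = cs[4],
                                thickness_d = cs[5])
    res <- simulate_rt(props, beam_geometry(), n_photons = 2e4,
                       seed = 1 + cs[1] * 100)
    expect_lt(abs(res$R_total + res$T_total + res$A_total + res$L_lateral - 1),
              1e-10)
    expect_true(all(c(res$R_total, res$T_total, res$A_total,
                      res$L_lateral) >= 0))
  }
})

test_that("no absorption with matched index loses nothing to A", {
  props <- optical_properties(0, 3, g = 0.6, n_sample = 1, thickness_d = 2)
  res <- simulate_rt(props, pencil_beam(), n_photons = 5e4, seed = 3)
  expect_identical(res$A_total, 0)
  expect_equal(res$R_total + res$T_total, 1, tolerance = 1e-12)
})

test_that("fixed seeds reproduce bit-identical tallies", {
  props <- optical_properties(0.05, 2, g = 0.75, n_sample = 1.41,
                              thickness_d = 2)
  a <- simulate_rt(props, beam_geometry(), n_photons = 2e4, seed = 99)
  b <- simulate_rt(props, beam_geometry(), n_photons = 2e4, seed = 99)
  c <- simulate_rt(props, beam_geometry(), n_photons = 2e4, seed = 100)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(a$R_total, c$R_total))
})

test_that("similarity relation holds in the diffusive regime", {
  # mu_a = 0, matched index: (mu_s = musp/(1-g), g = 0.75) vs (mu_s = musp,
  # g = 0) give the same R, T when the slab is optically thick
  musp <- 3; d <- 2 # reduced optical thickness 6
  hi_g <- optical_properties(0, musp, g = 0.75, n_sample = 1, thickness_d = d)
  iso <- optical_properties(0, musp, g = 0, n_sample = 1, thickness_d = d)
  r1 <- simulate_rt(hi_g, pencil_beam(), n_photons = 2e5, seed = 21)
  r2 <- simulate_rt(iso, pencil_beam(), n_photons = 2e5, seed = 22)
  expect_lt(abs(r1$R_total - r2$R_total), 0.01)
  expect_lt(abs(r1$T_total - r2$T_total), 0.01)
})

test_that("R grows with scattering and T falls with absorption beyond joint MC noise", {
  mua_grid <- c(0.001, 0.01, 0.05, 0.2, 0.5)
  musp_grid <- c(0.5, 1.5, 3, 5, 8)
  R <- matrix(0, 5, 5); T <- matrix(0, 5, 5); se <- matrix(0, 5, 5)
  seT <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    props <- optical_properties(mua_grid[i], musp_grid[j], g = 0.75,
                                n_sample = 1.41, thickness_d = 2)
    res <- simulate_rt(props, beam_geometry(), n_photons = 1e5,
                       seed = 1000 + i * 10 + j)
    R[i, j] <- res$R_total; T[i, j] <- res$T_total
    se[i, j] <- res$se_R; seT[i, j] <- res$se_T
  }
  for (i in 1:5) for (j in 1:4) # R non-decreasing in mu_s'
    expect_gt(R[i, j + 1] - R[i, j],
              -3 * sqrt(se[i, j]^2 + se[i, j + 1]^2))
  for (j in 1:5) for (i in 1:4) # T strictly decreasing in mu_a
    expect_gt(T[i, j] - T[i + 1, j],
              3 * sqrt(seT[i, j]^2 + seT[i + 1, j]^2))
})

test_that("Henyey-Greenstein sampling matches its closed-form inverse CDF", {
  expect_identical(sample_hg(0, 0.25), 2 * 0.25 - 1) # isotropic limit
  expect_equal(sample_hg(0, c(0, 0.5, 0.999)), c(-1, 0, 0.998))
  # median: evaluate the standard inversion formula independently
  g <- 0.75; u <- 0.5
  tmp <- (1 - g^2) / (1 - g + 2 * g * u)
  expect_equal(sample_hg(g, u), (1 + g^2 - tmp^2) / (2 * g))
  # mean of many draws equals g
  set.seed(8)
  draws <- sample_hg(0.75, runif(1e6))
  expect_true(all(draws >= -1 & draws <= 1))
  expect_lt(abs(mean(draws) - 0.75), 3 * sd(draws) / sqrt(1e6))
  expect_error(sample_hg(1, 0.5), "g")
})

test_that("unpolarized Fresnel coefficients hit the textbook anchors", {
  m <- fresnel_unpolarized(1.33, 1.33, 0.7)
  expect_identical(m$reflectance, 0)
  expect_identical(m$cos_theta_t, 0.7)
  expect_equal(fresnel_unpolarized(1, 1.5, 1)$reflectance, 0.04)
  # beyond the critical angle of a 1.5 -> 1 interface
  cos_super <- cos(asin(1 / 1.5) + 0.05)
  expect_identical(fresnel_unpolarized(1.5, 1, cos_super)$reflectance, 1)
  # Snell's law for the transmitted cosine
  out <- fresnel_unpolarized(1, 1.5, cos(pi / 6))
  expect_equal(out$cos_theta_t, sqrt(1 - (sin(pi / 6) / 1.5)^2))
  expect_error(fresnel_unpolarized(1, 1.5, 0), "cos_theta_i")
})

test_that("roulette is a no-op above threshold and unbiased below", {
  expect_identical(roulette(0.5, 1e-4, 0.1, 0.9), 0.5)
  expect_identical(roulette(1e-5, 1e-4, 0.1, 0.05), 1e-4)
  expect_identical(roulette(1e-5, 1e-4, 0.1, 0.5), 0)
  set.seed(12)
  n <- 1e6
  out <- roulette(rep(1e-5, n), 1e-4, 0.1, runif(n))
  se <- sd(out) / sqrt(n)
  expect_lt(abs(mean(out) - 1e-5), 3 * se)
})

test_that("invalid transport parameters are rejected naming the field", {
  expect_error(optical_properties(-0.1, 1), "mu_a")
  expect_error(optical_properties(0.1, -1), "mu_s_prime")
  expect_error(optical_properties(0.1, 1, g = 1), "g")
  expect_error(optical_properties(0.1, 1, n_sample = 0.9), "n_sample")
  expect_error(optical_properties(0.1, 1, thickness_d = 0), "thickness_d")
  expect_error(beam_geometry(incidence_deg = 90), "incidence_deg")
  expect_error(beam_geometry(beam_radius = 30, port_radius = 12), "beam_radius")
  props <- optical_properties(0.1, 1)
  expect_error(simulate_rt(props, beam_geometry(), n_photons = 0), "n_photons")
  expect_error(simulate_rt("x", beam_geometry()), "props")
})
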