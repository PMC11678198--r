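#' Ground-truth description of a photoluminescent phantom
#'
#' Parameterizes a silicone-like slab phantom loaded with scattering
#' particles and a fluorescent dye, emulating zirconia-in-silicone samples
#' doped with Rhodamine 6G: a power-law reduced scattering spectrum
#' \eqn{\mu_s'(\lambda) = \mu_{s,600}' (\lambda/600)^{-b}}, a flat matrix
#' absorption baseline plus a Gaussian dye band (peak 525 nm), and a Gaussian
#' photoluminescence emission band peaking at 548 nm (Stokes-shifted above
#' the absorption peak).
#'
#' @param musp_600 reduced scattering coefficient at 600 nm, 1/mm
#' @param scatter_power_b scattering power-law exponent (dimensionless)
#' @param dye_concentration dye concentration, wt% (0 = dye-free c0 sample)
#' @param dye_peak_nm absorption peak of the dye, nm
#' @param dye_bandwidth_nm FWHM of the dye absorption band, nm
#' @param dye_peak_mua_per_wt peak dye absorption per unit concentration,
#'   1/mm per wt%
#' @param baseline_mua matrix (dye-free) absorption, 1/mm, flat
#' @param pl_peak_nm photoluminescence emission peak, nm
#' @param pl_bandwidth_nm FWHM of the emission band, nm
#' @param pl_yield emitted/absorbed power fraction reaching the detector side
#' @param thickness_d slab thickness, mm (1, 2 or 4 in the standard series)
#' @param n_sample refractive index of the matrix
#' @return an object of class `phantom_truth`
#' @examples
#' phantom_truth(musp_600 = 4, dye_concentration = 4)
#' @export
phantom_truth <- function(musp_600 = 4, scatter_power_b = 1,
                          dye_concentration = 0, dye_peak_nm = 525,
                          dye_bandwidth_nm = 35, dye_peak_mua_per_wt = 0.03,
                          baseline_mua = 0.002, pl_peak_nm = 548,
                          pl_bandwidth_nm = 40, pl_yield = 0.2,
                          thickness_d = 2, n_sample = 1.41) {
  check_number(musp_600, "musp_600", lower = 0)
  check_number(scatter_power_b, "scatter_power_b")
  check_number(dye_concentration, "dye_concentration", lower = 0)
  check_number(dye_peak_nm, "dye_peak_nm", lower = 0, strict_lower = TRUE)
  check_number(dye_bandwidth_nm, "dye_bandwidth_nm", lower = 0,
               strict_lower = TRUE)
  check_number(dye_peak_mua_per_wt, "dye_peak_mua_per_wt", lower = 0)
  check_number(baseline_mua, "baseline_mua", lower = 0)
  check_number(pl_peak_nm, "pl_peak_nm", lower = 0, strict_lower = TRUE)
  if (pl_peak_nm <= dye_peak_nm)
    stop_field("pl_peak_nm",
               "must exceed dye_peak_nm (Stokes shift of the emission)")
  check_number(pl_bandwidth_nm, "pl_bandwidth_nm", lower = 0,
               strict_lower = TRUE)
  check_number(pl_yield, "pl_yield", lower = 0, upper = 1)
  check_number(thickness_d, "thickness_d", lower = 0, strict_lower = TRUE)
  check_number(n_sample, "n_sample", lower = 1)
  structure(list(musp_600 = musp_600, scatter_power_b = scatter_power_b,
                 dye_concentration = dye_concentration,
                 dye_peak_nm = dye_peak_nm,
                 dye_bandwidth_nm = dye_bandwidth_nm,
                 dye_peak_mua_per_wt = dye_peak_mua_per_wt,
                 baseline_mua = baseline_mua, pl_peak_nm = pl_peak_nm,
                 pl_bandwidth_nm = pl_bandwidth_nm, pl_yield = pl_yield,
                 thickness_d = thickness_d, n_sample = n_sample),
            class = "phantom_truth")
}

#' Shot-noise and dark-signal model of the detector
#'
#' @param shot_noise apply Poisson noise to the expected counts?
#' @param dark_rate dark signal, counts/s per emission bin
#' @param seed RNG seed for the generated dataset
#' @return an object of class `noise_model`
#' @export
noise_model <- function(shot_noise = TRUE, dark_rate = 0, seed = 1) {
  check_number(dark_rate, "dark_rate", lower = 0)
  check_number(seed, "seed")
  structure(list(shot_noise = isTRUE(shot_noise), dark_rate = dark_rate,
                 seed = seed), class = "noise_model")
}

gaussian_band <- function(x, center, fwhm) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  exp(-(x - center)^2 / (2 * s^2))
}

#' True optical-property spectra of a phantom
#'
#' @param phantom a [phantom_truth]
#' @param wavelengths nm
#' @return `data.frame` with columns `wavelength`, `mu_a`, `mu_s_prime`
#' @export
truth_spectra <- function(phantom, wavelengths) {
  if (!inherits(phantom, "phantom_truth"))
    stop_field("phantom", "must be a phantom_truth")
  musp <- phantom$musp_600 * (wavelengths / 600)^(-phantom$scatter_power_b)
  mua <- phantom$baseline_mua + phantom$dye_concentration *
    phantom$dye_peak_mua_per_wt *
    gaussian_band(wavelengths, phantom$dye_peak_nm, phantom$dye_bandwidth_nm)
  data.frame(wavelength = wavelengths, mu_a = mua, mu_s_prime = musp)
}

# compactly supported elastic line profile: Gaussian of FWHM `fwhm`
# truncated strictly inside +-trunc and renormalized to unit area. With
# trunc one grid step inside the half-window, the 10 nm elastic window
# captures the whole line and neighbouring excitation rows contribute
# exactly zero to it, so the window integrals cancel exactly in the
# calibration ratios.
elastic_profile <- function(emission, center, fwhm = 7, trunc = 4) {
  y <- gaussian_band(emission, center, fwhm)
  y[abs(emission - center) >= trunc] <- 0
  area <- sum(diff(emission) * (head(y, -1) + y[-1]) / 2)
  if (area > 0) y / area else y
}

# forward engine dispatch: returns c(R_eff, T_eff) at one wavelength
forward_effective_rt <- function(engine, mua, musp, phantom, beam, sphere,
                                 rho_cal, n_photons, seed, wavelength) {
  if (inherits(engine, "lookup_table")) {
    ip <- lut_interp(engine, mua, musp)
    if (mua < min(engine$mua_grid) || mua > max(engine$mua_grid) ||
        musp < min(engine$musp_grid) || musp > max(engine$musp_grid))
      stop(sprintf("forward lookup table does not cover wavelength %g nm (mu_a = %g, mu_s' = %g)",
                   wavelength, mua, musp), call. = FALSE)
    c(R = ip$R, T = ip$T, A = max(0, 1 - ip$R - ip$T))
  } else if (identical(engine, "mc")) {
    props <- optical_properties(mua, musp, g = 0.75,
                                n_sample = phantom$n_sample,
                                thickness_d = phantom$thickness_d)
    res <- simulate_rt(props, beam, n_photons = n_photons, seed = seed)
    eff <- effective_rt(res$R_total, res$T_total, sphere, rho_cal = rho_cal,
                        wavelength_nm = wavelength)
    c(R = eff$R_eff, T = eff$T_eff, A = res$A_total)
  } else stop_field("engine", "must be a lookup_table or \"mc\"")
}

#' Generate a synthetic seven-channel measurement set
#'
#' Emulates the full measurement routine for one phantom: the four
#' calibration channels (mirror, open port) and the three sample channels,
#' each as an excitation-resolved emission scan. Expected elastic signals
#' are constructed from the sphere radiation-exchange model so that the
#' calibration algebra applied to noise-free output returns exactly the
#' forward engine's effective reflectance and transmittance. The sample
#' channels additionally carry a Gaussian photoluminescence band whose
#' amplitude tracks the excitation power absorbed by the dye times
#' `pl_yield`, split evenly between the reflection and transmission
#' directions. Photoluminescence is injected at the signal level, not
#' transported through the Monte Carlo.
#'
#' @param phantom a [phantom_truth]
#' @param sphere a [sphere_geometry]
#' @param noise a [noise_model]
#' @param engine forward model: a sphere-corrected [build_lut()] table whose
#'   grid covers the phantom's property range, or the string `"mc"` to run
#'   the Monte Carlo at every wavelength
#' @param excitation_grid excitation wavelengths, nm
#' @param emission_step emission grid spacing, nm
#' @param rho_cal calibration-mirror reflectance (scalar or table as in
#'   [signal_set()])
#' @param beam a [beam_geometry] (used by the `"mc"` engine)
#' @param n_photons photons per wavelength for the `"mc"` engine
#' @param lamp_scale lamp signal scale, counts/s at the detector
#' @param n_averages acquisitions averaged per excitation wavelength
#' @return list with `scans` (named list of seven [spectral_scan]s),
#'   `rho_cal`, `truth` (the phantom's property spectra) and `seed`
#' @export
generate_channels <- function(phantom, sphere = sphere_geometry(),
                              noise = noise_model(shot_noise = FALSE),
                              engine = "mc",
                              excitation_grid = seq(320, 1000, by = 10),
                              emission_step = 2, rho_cal = 0.98,
                              beam = beam_geometry(), n_photons = 1e5,
                              lamp_scale = 1e6, n_averages = 10) {
  if (!inherits(phantom, "phantom_truth"))
    stop_field("phantom", "must be a phantom_truth")
  if (!inherits(noise, "noise_model"))
    stop_field("noise", "must be a noise_model")
  exc <- excitation_grid
  emission <- seq(min(exc) - 10, max(exc) + 10, by = emission_step)
  truth <- truth_spectra(phantom, exc)
  acq <- acquisition_schedule(exc)
  rc <- if (is.data.frame(rho_cal))
    approx(rho_cal$wavelength_nm, rho_cal$reflectance, xout = exc)$y
  else rep(rho_cal, length(exc))

  # smooth lamp emission profile (arbitrary units); broad thermal-like hump
  lamp <- lamp_scale * (0.25 + gaussian_band(exc, 700, 600))

  channels <- c("CRBR", "CNBR", "CNBT", "CTBT", "SRB", "SNB", "STB")
  rates <- setNames(vector("list", length(channels)), channels)
  for (ch in channels)
    rates[[ch]] <- matrix(0, length(exc), length(emission))

  pl_shape <- gaussian_band(emission, phantom$pl_peak_nm,
                            phantom$pl_bandwidth_nm)
  pl_area <- sum(diff(emission) * (head(pl_shape, -1) + pl_shape[-1]) / 2)
  pl_shape <- if (pl_area > 0) pl_shape / pl_area else pl_shape

  for (k in seq_along(exc)) {
    wl <- exc[k]
    rho_w <- wall_reflectance_at(sphere, wl)
    fw <- forward_effective_rt(engine, truth$mu_a[k], truth$mu_s_prime[k],
                               phantom, beam, sphere, rc[k],
                               n_photons, seed = noise$seed + k, wl)
    # sphere gains with the port closed by sample, mirror, nothing
    M_R <- sphere_gain(sphere, min(1, fw["R"]), wl)
    M_cal <- sphere_gain(sphere, rc[k], wl)
    M_0 <- sphere_gain(sphere, 0, wl)
    line <- elastic_profile(emission, wl)

    # detector rates of the seven channels (counts/s per nm, on `line`).
    # The forward engine already reports sphere-referred (measured-space)
    # R and T, so the channels carry the configuration gains -- which the
    # calibration algebra cancels exactly -- while the direct-view bias
    # stays inside the engine's effective map.
    el <- list(
      CRBR = lamp[k] * rc[k] * M_cal,
      CNBR = lamp[k] * rho_w * M_cal,
      CNBT = lamp[k] * rho_w * M_0,
      CTBT = lamp[k] * M_0,
      SRB  = lamp[k] * fw["R"] * M_R,
      SNB  = lamp[k] * rho_w * M_R,
      STB  = lamp[k] * fw["T"] * M_R)
    for (ch in channels)
      rates[[ch]][k, ] <- el[[ch]] * line

    # photoluminescence: absorbed power times the dye's share of mu_a,
    # times the yield, emitted in the Stokes-shifted band
    mua_dye <- truth$mu_a[k] - phantom$baseline_mua
    if (phantom$pl_yield > 0 && mua_dye > 0 && truth$mu_a[k] > 0) {
      absorbed <- fw["A"] * mua_dye / truth$mu_a[k]
      pl_power <- lamp[k] * absorbed * phantom$pl_yield * M_R
      # the emission that would fall under this row's own elastic peak is
      # suppressed: the generator idealizes perfect elastic/PL separability
      # at every excitation wavelength (see the methods vignette)
      pl_row <- pl_shape
      pl_row[abs(emission - wl) <= 6] <- 0
      rates$SRB[k, ] <- rates$SRB[k, ] + 0.5 * pl_power * pl_row
      rates$STB[k, ] <- rates$STB[k, ] + 0.5 * pl_power * pl_row
    }
  }

  dark <- rep(noise$dark_rate, length(emission))
  scans <- with_seed(noise$seed, {
    lapply(setNames(channels, channels), function(ch) {
      expected <- (rates[[ch]] + noise$dark_rate) * acq * n_averages
      counts <- if (noise$shot_noise)
        matrix(as.double(rpois(length(expected), expected)),
               nrow = nrow(expected))
      else expected
      spectral_scan(ch, exc, emission, counts, acquisition_time = acq,
                    n_averages = n_averages, dark_spectrum = dark)
    })
  })
  list(scans = scans, rho_cal = data.frame(wavelength_nm = exc,
                                           reflectance = rc),
       truth = truth, seed = noise$seed)
}

#' Build the concentration-by-scatterer sample matrix
#'
#' Cartesian product of dye concentrations, particle loadings (as reduced
#' scattering at 600 nm) and thicknesses, with a dye-free c0 phantom
#' included for every particle level -- the layout of the standard
#' validation batch (four concentrations plus c0, three particle levels).
#'
#' @param concentrations dye concentrations, wt%
#' @param particle_levels reduced scattering at 600 nm, 1/mm
#' @param thicknesses slab thicknesses, mm
#' @param ... further arguments passed to [phantom_truth()]
#' @return list of [phantom_truth] objects
#' @export
matrix_of_samples <- function(concentrations = c(2.66, 4, 5.33, 6.66),
                              particle_levels = c(2, 4, 6),
                              thicknesses = 2, ...) {
  if (length(concentrations) == 0 || length(particle_levels) == 0 ||
      length(thicknesses) == 0)
    stop_field("concentrations", "all input lists must be non-empty")
  conc <- unique(c(0, concentrations))
  grid <- expand.grid(concentration = conc, musp = particle_levels,
                      d = thicknesses)
  lapply(seq_len(nrow(grid)), function(i)
    phantom_truth(musp_600 = grid$musp[i],
                  dye_concentration = grid$concentration[i],
                  thickness_d = grid$d[i], ...))
}
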