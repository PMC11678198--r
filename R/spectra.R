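#' Excitation-resolved emission scan of one measurement channel
#'
#' One channel of the measurement routine: for every excitation wavelength a
#' full emission spectrum is recorded. The seven channels are the calibration
#' set `CRBR` (mirror, reflection beam), `CNBR` (mirror, normalization beam),
#' `CNBT` (open port, normalization beam), `CTBT` (open port, transmission
#' beam) and the sample set `SRB`, `SNB`, `STB`.
#'
#' `counts` holds raw detector counts accumulated over `n_averages`
#' acquisitions of `acquisition_time` seconds each; `dark_spectrum` is the
#' dark signal rate (counts/s) on the same emission grid, measured before the
#' scan with matching acquisition settings and already time-normalized, so
#' one dark spectrum serves all excitation bands despite their different
#' acquisition times.
#'
#' @param channel_id one of CRBR, CNBR, CNBT, CTBT, SRB, SNB, STB
#' @param excitation_grid excitation wavelengths, nm, strictly ascending
#' @param emission_grid emission wavelengths, nm, strictly ascending
#' @param counts matrix, `length(excitation_grid)` x `length(emission_grid)`
#' @param acquisition_time seconds per acquisition: scalar or one value per
#'   excitation wavelength
#' @param n_averages number of averaged acquisitions
#' @param dark_spectrum dark count rate, counts/s, on `emission_grid`
#' @return an object of class `spectral_scan`
#' @export
spectral_scan <- function(channel_id, excitation_grid, emission_grid, counts,
                          acquisition_time, n_averages = 10,
                          dark_spectrum = numeric(length(emission_grid))) {
  channels <- c("CRBR", "CNBR", "CNBT", "CTBT", "SRB", "SNB", "STB")
  if (!is.character(channel_id) || length(channel_id) != 1L ||
      !channel_id %in% channels)
    stop_field("channel_id", paste("must be one of",
                                   paste(channels, collapse = ", ")))
  if (is.unsorted(excitation_grid, strictly = TRUE))
    stop_field("excitation_grid", "must be strictly ascending")
  if (is.unsorted(emission_grid, strictly = TRUE))
    stop_field("emission_grid", "must be strictly ascending")
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(length(excitation_grid), length(emission_grid))))
    stop_field("counts", "must be excitation x emission")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_field("counts", "must be finite and >= 0")
  if (length(acquisition_time) == 1L)
    acquisition_time <- rep(acquisition_time, length(excitation_grid))
  if (length(acquisition_time) != length(excitation_grid) ||
      any(acquisition_time <= 0))
    stop_field("acquisition_time", "must be > 0, one value per excitation")
  check_number(n_averages, "n_averages", lower = 1)
  if (length(dark_spectrum) != length(emission_grid))
    stop_field("dark_spectrum", "must match the emission grid")
  structure(list(channel_id = channel_id,
                 excitation_grid = excitation_grid,
                 emission_grid = emission_grid,
                 counts = counts,
                 acquisition_time = acquisition_time,
                 n_averages = n_averages,
                 dark_spectrum = dark_spectrum,
                 preprocessed = FALSE, n_clipped = 0L),
            class = "spectral_scan")
}

#' @export
print.spectral_scan <- function(x, ...) {
  cat(sprintf("Spectral scan %s: %d excitation x %d emission wavelengths%s\n",
              x$channel_id, length(x$excitation_grid),
              length(x$emission_grid),
              if (x$preprocessed) " (preprocessed, counts/s)" else " (raw)"))
  invisible(x)
}

#' Acquisition-time schedule of the measurement routine
#'
#' Spectral acquisition times per excitation band: 100 ms for 320-340 nm,
#' 50 ms for 350-600 nm, 100 ms for 610-690 nm and 200 ms from 700 nm up,
#' compensating the lamp, grating and detector response across the band.
#'
#' @param excitation_grid excitation wavelengths, nm
#' @return acquisition times in seconds, one per wavelength
#' @export
acquisition_schedule <- function(excitation_grid) {
  ifelse(excitation_grid < 350, 0.1,
         ifelse(excitation_grid <= 600, 0.05,
                ifelse(excitation_grid < 700, 0.1, 0.2)))
}

#' Dark-subtract and normalize a scan to count rates
#'
#' Divides accumulated counts by the number of averages and the per-band
#' acquisition time, then subtracts the dark rate, leaving net counts per
#' second. Negative residuals after dark subtraction are clipped to zero and
#' their number recorded in the `n_clipped` field.
#'
#' @param scan a raw [spectral_scan]
#' @return the scan with `counts` in counts/s and `preprocessed = TRUE`
#' @export
preprocess <- function(scan) {
  if (!inherits(scan, "spectral_scan"))
    stop_field("scan", "must be a spectral_scan")
  if (scan$preprocessed) return(scan)
  rate <- scan$counts / scan$n_averages / scan$acquisition_time
  net <- sweep(rate, 2, scan$dark_spectrum, "-")
  n_clip <- sum(net < 0)
  net[net < 0] <- 0
  scan$counts <- net
  scan$preprocessed <- TRUE
  scan$n_clipped <- as.integer(n_clip)
  scan
}

# trapezoidal integral of one emission row over [lo, hi], with linear
# interpolation at the window edges so adjacent windows partition exactly
integrate_window <- function(emission, y, lo, hi) {
  if (lo < emission[1] || hi > emission[length(emission)])
    stop("integration window extends past the emission grid", call. = FALSE)
  inside <- emission > lo & emission < hi
  xs <- c(lo, emission[inside], hi)
  ys <- c(approx(emission, y, xout = lo)$y, y[inside],
          approx(emission, y, xout = hi)$y)
  sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2)
}

#' Integrate the elastic-scattering peak of one excitation row
#'
#' Trapezoidal integral of the emission spectrum over the 10 nm window
#' centred on the excitation wavelength -- the elastically scattered light
#' entering the reflectance/transmittance calculation, excluding the
#' wavelength-shifted photoluminescence.
#'
#' @param scan a preprocessed [spectral_scan]
#' @param excitation excitation wavelength, nm; must be on the grid
#' @param window_nm full window width, nm
#' @return integrated elastic signal, counts/s x nm
#' @export
integrate_elastic <- function(scan, excitation, window_nm = 10) {
  if (!inherits(scan, "spectral_scan"))
    stop_field("scan", "must be a spectral_scan")
  k <- match(excitation, scan$excitation_grid)
  if (is.na(k))
    stop_field("excitation", "not on the excitation grid")
  check_number(window_nm, "window_nm", lower = 0, strict_lower = TRUE)
  integrate_window(scan$emission_grid, scan$counts[k, ],
                   excitation - window_nm / 2, excitation + window_nm / 2)
}

#' Extract the photoluminescence spectrum of one excitation row
#'
#' Returns the emission spectrum with the elastic window masked (`NA`), i.e.
#' the wavelength-shifted photoluminescence recorded alongside the elastic
#' signal. Masked bins stay visible as `NA` rather than being zeroed.
#'
#' @inheritParams integrate_elastic
#' @return `data.frame` with columns `emission_nm`, `rate` (counts/s, `NA`
#'   inside the elastic window)
#' @export
extract_pl <- function(scan, excitation, window_nm = 10) {
  if (!inherits(scan, "spectral_scan"))
    stop_field("scan", "must be a spectral_scan")
  k <- match(excitation, scan$excitation_grid)
  if (is.na(k))
    stop_field("excitation", "not on the excitation grid")
  rate <- scan$counts[k, ]
  mask <- scan$emission_grid >= excitation - window_nm / 2 &
    scan$emission_grid <= excitation + window_nm / 2
  rate[mask] <- NA_real_
  data.frame(emission_nm = scan$emission_grid, rate = rate)
}

#' Seven-channel signal set entering the calibration algebra
#'
#' Collapses the seven channel scans to one integrated elastic signal per
#' excitation wavelength (or, in polychromatic mode, to the broadband signal
#' a white-light setup would record: the emission spectra of all excitation
#' rows summed, then integrated in the same window -- which folds the
#' photoluminescence into the apparent elastic signal).
#'
#' @param scans named list with elements CRBR, CNBR, CNBT, CTBT, SRB, SNB,
#'   STB, each a [spectral_scan] on a common excitation grid
#' @param rho_cal mirror hemispherical reflectance: scalar or `data.frame`
#'   with columns `wavelength_nm`, `reflectance` (interpolated linearly)
#' @param mode `"monochromatic"` or `"polychromatic"`
#' @param window_nm elastic integration window, nm
#' @return an object of class `signal_set`: `data.frame` with the seven
#'   integrated signals and `rho_cal` per excitation wavelength
#' @export
signal_set <- function(scans, rho_cal,
                       mode = c("monochromatic", "polychromatic"),
                       window_nm = 10) {
  mode <- match.arg(mode)
  need <- c("CRBR", "CNBR", "CNBT", "CTBT", "SRB", "SNB", "STB")
  if (!all(need %in% names(scans)))
    stop_field("scans", paste("needs channels",
                              paste(need, collapse = ", ")))
  scans <- lapply(scans[need], preprocess)
  exc <- scans$SRB$excitation_grid
  for (ch in need)
    if (!isTRUE(all.equal(scans[[ch]]$excitation_grid, exc)))
      stop_field("scans", "excitation grids differ between channels")

  integrate_channel <- function(scan) {
    counts <- scan$counts
    if (mode == "polychromatic") {
      # broadband illumination: all excitation rows arrive at once
      total <- colSums(counts)
      counts <- matrix(total, nrow = length(exc), ncol = ncol(counts),
                       byrow = TRUE)
    }
    vapply(seq_along(exc), function(k)
      integrate_window(scan$emission_grid, counts[k, ],
                       exc[k] - window_nm / 2, exc[k] + window_nm / 2),
      numeric(1))
  }
  sig <- as.data.frame(lapply(scans, integrate_channel))
  rc <- if (is.data.frame(rho_cal)) {
    if (any(exc < min(rho_cal$wavelength_nm)) ||
        any(exc > max(rho_cal$wavelength_nm)))
      stop_field("rho_cal", "table does not cover the excitation grid")
    approx(rho_cal$wavelength_nm, rho_cal$reflectance, xout = exc)$y
  } else rep(rho_cal, length(exc))
  if (any(rc <= 0) || any(rc > 1))
    stop_field("rho_cal", "must lie in (0, 1]")
  out <- cbind(data.frame(wavelength = exc), sig, rho_cal = rc)
  class(out) <- c("signal_set", "data.frame")
  attr(out, "mode") <- mode
  out
}

#' Reflectance and transmittance from the seven-channel signals
#'
#' The calibration algebra of the single-sphere substitution routine:
#' \deqn{R = \frac{S_{RB} \, C_{NBR}}{S_{NB} \, C_{RBR}} \rho_{cal}, \qquad
#'       T = \frac{S_{TB} \, C_{NBT}}{S_{NB} \, C_{TBT}}}
#' The normalization-beam ratios cancel lamp drift and the substitution
#' change of the sphere gain. Wavelengths with a zero denominator are
#' flagged and excluded from the output.
#'
#' @param signals a [signal_set]
#' @return an object of class `rt_spectrum`: `data.frame` with columns
#'   `wavelength`, `R`, `T` and attributes `mode` and `excluded` (flagged
#'   wavelengths)
#' @examples
#' # mirror remeasured as the sample: R equals rho_cal
#' @export
compute_rt <- function(signals) {
  if (!inherits(signals, "signal_set"))
    stop_field("signals", "must be a signal_set")
  bad <- signals$SNB <= 0 | signals$CRBR <= 0 | signals$CTBT <= 0
  ok <- !bad
  R <- signals$SRB[ok] * signals$CNBR[ok] /
    (signals$SNB[ok] * signals$CRBR[ok]) * signals$rho_cal[ok]
  T <- signals$STB[ok] * signals$CNBT[ok] /
    (signals$SNB[ok] * signals$CTBT[ok])
  out <- data.frame(wavelength = signals$wavelength[ok], R = R, T = T)
  class(out) <- c("rt_spectrum", "data.frame")
  attr(out, "mode") <- attr(signals, "mode")
  attr(out, "excluded") <- signals$wavelength[bad]
  out
}

#' Broadband (polychromatic) analysis of the channel scans
#'
#' Convenience wrapper reproducing what a classical white-light integrating
#' sphere setup reports: the analysis cannot separate elastic scattering
#' from photoluminescence, so both enter the signals, which distorts R and T
#' wherever the sample luminesces. Used to demonstrate the artifact; the
#' monochromatic route via [signal_set()] + [compute_rt()] is the correct
#' analysis.
#'
#' @inheritParams signal_set
#' @return an `rt_spectrum` with `mode = "polychromatic"`
#' @export
compute_rt_polychromatic <- function(scans, rho_cal, window_nm = 10) {
  compute_rt(signal_set(scans, rho_cal, mode = "polychromatic",
                        window_nm = window_nm))
}

#' Concentration-normalized dye absorption spectrum
#'
#' Subtracts the absorption spectrum of the dye-free sample (c0) and divides
#' by the dye concentration, giving the specific absorption of the dye in
#' 1/mm per wt%. If the dye obeys Beer's law the normalized spectra of all
#' concentrations collapse onto one curve. Negative excursions beyond
#' `3 * sigma` are flagged (count in attribute `n_negative`), not clipped:
#' they indicate baseline or inversion problems the user should see.
#'
#' @param mua_sample `data.frame` with columns `wavelength`, `mu_a` for the
#'   dye-loaded sample
#' @param mua_baseline_c0 same layout, for the dye-free sample; wavelength
#'   grids must match
#' @param concentration dye concentration, wt% (> 0)
#' @param sigma optional per-wavelength uncertainty of the difference, used
#'   for the negative-excursion flag
#' @return `data.frame` with columns `wavelength`, `mu_a_per_wt`
#' @export
dye_absorption <- function(mua_sample, mua_baseline_c0, concentration,
                           sigma = 0) {
  if (!identical(mua_sample$wavelength, mua_baseline_c0$wavelength))
    stop_field("mua_baseline_c0", "wavelength grids must match")
  check_number(concentration, "concentration", lower = 0, strict_lower = TRUE)
  diff_mua <- mua_sample$mu_a - mua_baseline_c0$mu_a
  out <- data.frame(wavelength = mua_sample$wavelength,
                    mu_a_per_wt = diff_mua / concentration)
  attr(out, "n_negative") <- sum(diff_mua < -3 * sigma)
  out
}
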