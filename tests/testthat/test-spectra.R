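# Spectral processing: preprocessing, elastic-peak integration, the
# calibration algebra and the elastic/photoluminescence partition.

make_scan <- function(rates, exc, em, acq = 0.05, n_avg = 10, dark = 0,
                      channel = "SRB") {
  # rates in counts/s -> raw accumulated counts
  counts <- (rates + dark) * acq * n_avg
  spectral_scan(channel, exc, em, counts, acquisition_time = acq,
                n_averages = n_avg, dark_spectrum = rep(dark, length(em)))
}

test_that("preprocessing recovers injected rates and clips dark residuals", {
  exc <- c(500, 510); em <- seq(480, 540, by = 2)
  rates <- matrix(rep(c(100, 200), length(em)), nrow = 2)
  scan <- make_scan(rates, exc, em, acq = 0.05, dark = 7)
  pp <- preprocess(scan)
  expect_equal(pp$counts, rates, tolerance = 1e-12)
  expect_identical(pp$n_clipped, 0L)
  # data identical to dark -> all-zero rates
  zero <- make_scan(matrix(0, 2, length(em)), exc, em, dark = 7)
  expect_true(all(preprocess(zero)$counts == 0))
  # acquisition-time normalization: same counts, half the time, double rate
  s1 <- spectral_scan("SNB", exc, em, matrix(50, 2, length(em)), 0.2, 1)
  s2 <- spectral_scan("SNB", exc, em, matrix(50, 2, length(em)), 0.1, 1)
  expect_equal(preprocess(s2)$counts, 2 * preprocess(s1)$counts)
  # dark exceeding signal is clipped and counted
  hot <- make_scan(matrix(1, 2, length(em)), exc, em, dark = 5)
  hot$dark_spectrum <- rep(10, length(em))
  pp_hot <- preprocess(hot)
  expect_true(all(pp_hot$counts == 0))
  expect_identical(pp_hot$n_clipped, 2L * length(em))
})

test_that("preprocessing is idempotent and shot noise averages out", {
  exc <- seq(500, 540, by = 10); em <- seq(480, 580, by = 2)
  rate <- 5000
  set.seed(31)
  counts <- matrix(rpois(length(exc) * length(em), rate * 0.05 * 10),
                   nrow = length(exc))
  scan <- spectral_scan("STB", exc, em, counts, 0.05, 10,
                        rep(0, length(em)))
  pp <- preprocess(scan)
  expect_identical(preprocess(pp), pp)
  # mean recovered rate within a few shot-noise standard errors
  se <- sqrt(rate / (0.05 * 10)) / sqrt(length(counts))
  expect_lt(abs(mean(pp$counts) - rate), 4 * se)
})

test_that("elastic integration captures a contained peak and excludes the Stokes band", {
  exc <- seq(500, 560, by = 10); em <- seq(450, 650, by = 1)
  peak_area <- 1234
  rates <- matrix(0, length(exc), length(em))
  for (k in seq_along(exc)) {
    prof <- exp(-(em - exc[k])^2 / (2 * 1.2^2))
    rates[k, ] <- peak_area * prof / sum(diff(em) * (prof[-1] + prof[-length(prof)]) / 2)
  }
  scan <- make_scan(rates, exc, em)
  pp <- preprocess(scan)
  # narrow peak fully inside the window: total area recovered
  expect_equal(integrate_elastic(pp, 520), peak_area, tolerance = 1e-3)
  # PL band at 548 nm does not touch the 520 nm elastic window
  pl <- 50 * exp(-(em - 548)^2 / (2 * 5^2))
  scan2 <- make_scan(sweep(rates, 2, pl, "+"), exc, em)
  pp2 <- preprocess(scan2)
  el_with_pl <- integrate_elastic(pp2, 520)
  expect_equal(el_with_pl, peak_area, tolerance = 2e-3)
  expect_error(integrate_elastic(pp, 515), "excitation")
  expect_error(integrate_elastic(pp, 500, window_nm = 200), "emission grid")
})

test_that("the captured fraction of a 7 nm FWHM excitation line matches the error-function integral", {
  em <- seq(400, 700, by = 0.5)
  exc <- 550
  sigma <- 7 / (2 * sqrt(2 * log(2)))
  prof <- exp(-(em - exc)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  scan <- make_scan(matrix(prof, 1, length(em)), exc, em)
  pp <- preprocess(scan)
  captured <- integrate_elastic(pp, exc)
  # closed form: a +-5 nm window on a sigma = 2.97 nm line holds 90.7% of
  # the area (the remainder spills into the neighbouring bands)
  analytic <- 2 * pnorm(5 / sigma) - 1
  expect_equal(captured, analytic, tolerance = 2e-3)
  expect_gt(captured, 0.9)
})

test_that("the elastic window and the photoluminescence remainder partition the spectrum", {
  exc <- 520; em <- seq(420, 640, by = 2)
  rates <- 300 * exp(-(em - exc)^2 / (2 * 3^2)) +
    80 * exp(-(em - 548)^2 / (2 * 17^2))
  scan <- make_scan(matrix(rates, 1, length(em)), exc, em)
  pp <- preprocess(scan)
  elastic <- integrate_elastic(pp, exc)
  pl <- extract_pl(pp, exc)
  expect_true(all(is.na(pl$rate[abs(pl$emission_nm - exc) <= 5])))
  expect_false(any(is.na(pl$rate[abs(pl$emission_nm - exc) > 5])))
  # integrate the remainder with the same edge-split trapezoid
  total <- lumisphere:::integrate_window(em, rates, min(em), max(em))
  left <- lumisphere:::integrate_window(em, rates, min(em), exc - 5)
  right <- lumisphere:::integrate_window(em, rates, exc + 5, max(em))
  expect_equal(elastic + left + right, total, tolerance = 1e-12)
})

test_that("the calibration algebra reproduces its closed-form anchors", {
  exc <- c(500, 600)
  base <- list(SRB = c(50, 60), SNB = c(200, 210), STB = c(70, 80),
               CRBR = c(100, 110), CNBR = c(180, 190), CNBT = c(160, 170),
               CTBT = c(150, 160))
  em <- seq(480, 630, by = 1)
  scans <- lapply(names(base), function(ch) {
    rates <- matrix(0, 2, length(em))
    for (k in 1:2) {
      prof <- exp(-(em - exc[k])^2 / (2 * 1.5^2))
      prof <- prof / lumisphere:::integrate_window(em, prof, exc[k] - 5,
                                                   exc[k] + 5)
      rates[k, ] <- base[[ch]][k] * prof
    }
    make_scan(rates, exc, em, channel = ch)
  })
  names(scans) <- names(base)

  # hand-evaluated quotient at 500 nm: (50/200) * (180/100) * 0.95 = 0.4275
  rt <- compute_rt(signal_set(scans, rho_cal = 0.95))
  expect_equal(rt$R[1], 0.4275, tolerance = 1e-6)
  expect_equal(rt$T[1], (70 / 200) * (160 / 150), tolerance = 1e-6)

  # mirror remeasured as the sample: R = rho_cal exactly
  mirror <- scans
  mirror$SRB <- scans$CRBR; mirror$SRB$channel_id <- "SRB"
  mirror$SNB <- scans$CNBR; mirror$SNB$channel_id <- "SNB"
  rt_mirror <- compute_rt(signal_set(mirror, rho_cal = 0.98))
  expect_equal(rt_mirror$R, c(0.98, 0.98), tolerance = 1e-9)

  # open port remeasured: T = 1 exactly
  open <- scans
  open$STB <- scans$CTBT; open$STB$channel_id <- "STB"
  open$SNB <- scans$CNBT; open$SNB$channel_id <- "SNB"
  rt_open <- compute_rt(signal_set(open, rho_cal = 0.98))
  expect_equal(rt_open$T, c(1, 1), tolerance = 1e-9)

  # lamp drift: scaling sample and calibration sets by common factors
  # leaves R and T unchanged
  drift <- scans
  for (ch in c("SRB", "SNB", "STB")) drift[[ch]]$counts <-
      drift[[ch]]$counts * 1.37
  for (ch in c("CRBR", "CNBR", "CNBT", "CTBT")) drift[[ch]]$counts <-
      drift[[ch]]$counts * 0.81
  rt_drift <- compute_rt(signal_set(drift, rho_cal = 0.95))
  expect_equal(rt_drift$R, rt$R, tolerance = 1e-12)
  expect_equal(rt_drift$T, rt$T, tolerance = 1e-12)

  # a dead normalization channel flags the wavelength instead of dividing
  dead <- scans
  dead$SNB$counts[1, ] <- 0
  rt_dead <- compute_rt(signal_set(dead, rho_cal = 0.95))
  expect_equal(nrow(rt_dead), 1)
  expect_equal(attr(rt_dead, "excluded"), 500)
})

test_that("concentration-normalized dye spectra collapse and diagnose negatives", {
  wl <- seq(450, 650, by = 10)
  base <- data.frame(wavelength = wl, mu_a = 0.002 + 0 * wl)
  dye <- function(conc) data.frame(
    wavelength = wl,
    mu_a = 0.002 + conc * 0.03 * exp(-(wl - 525)^2 / (2 * 15^2)))
  n1 <- dye_absorption(dye(2.66), base, 2.66)
  n2 <- dye_absorption(dye(6.66), base, 6.66)
  expect_equal(n1$mu_a_per_wt, n2$mu_a_per_wt, tolerance = 1e-12)
  same <- dye_absorption(base, base, 4)
  expect_true(all(same$mu_a_per_wt == 0))
  # negative excursions beyond 3 sigma are flagged, not clipped
  dipped <- base; dipped$mu_a[3] <- base$mu_a[3] - 0.01
  flagged <- dye_absorption(dipped, base, 4, sigma = 1e-4)
  expect_identical(attr(flagged, "n_negative"), 1L)
  expect_lt(flagged$mu_a_per_wt[3], 0)
  shifted <- base; shifted$wavelength <- wl + 5
  expect_error(dye_absorption(shifted, base, 4), "wavelength")
})
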