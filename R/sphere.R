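#' Single integrating-sphere geometry
#'
#' Geometry and coating of a single integrating sphere with four ports
#' (sample, reflection beam, normalization beam, detection) and no baffles.
#' The default values describe a 150 mm sphere with a 25 mm sample port,
#' three 20 mm auxiliary ports, a detector viewing a 6 mm spot of the wall
#' and a barium-sulfate coating of hemispherical reflectance 0.97 (flat by
#' default, or tabulated against wavelength as a `data.frame` with columns
#' `wavelength_nm`, `reflectance`).
#'
#' @param sphere_diameter inner sphere diameter, mm
#' @param wall_reflectance wall reflectance, fraction in (0, 1); scalar or
#'   two-column table
#' @param port_diameters named numeric vector with entries `sample`,
#'   `reflection`, `normalization`, `detection` in mm
#' @param detector_view_diameter diameter of the wall area seen by the
#'   detector, mm
#' @return an object of class `sphere_geometry`
#' @examples
#' sphere_geometry()
#' @export
sphere_geometry <- function(sphere_diameter = 150,
                            wall_reflectance = 0.97,
                            port_diameters = c(sample = 25, reflection = 20,
                                               normalization = 20,
                                               detection = 20),
                            detector_view_diameter = 6) {
  check_number(sphere_diameter, "sphere_diameter", lower = 0,
               strict_lower = TRUE)
  need <- c("sample", "reflection", "normalization", "detection")
  if (!is.numeric(port_diameters) || !all(need %in% names(port_diameters)))
    stop_field("port_diameters",
               "needs named entries sample, reflection, normalization, detection")
  port_diameters <- port_diameters[need]
  if (any(port_diameters <= 0) || any(port_diameters >= sphere_diameter))
    stop_field("port_diameters", "must be positive and below sphere_diameter")
  check_number(detector_view_diameter, "detector_view_diameter", lower = 0,
               strict_lower = TRUE)
  if (is.numeric(wall_reflectance) && length(wall_reflectance) == 1L) {
    check_number(wall_reflectance, "wall_reflectance", lower = 0, upper = 1,
                 strict_lower = TRUE, strict_upper = TRUE)
  } else if (is.data.frame(wall_reflectance)) {
    if (!all(c("wavelength_nm", "reflectance") %in% names(wall_reflectance)))
      stop_field("wall_reflectance",
                 "table needs columns wavelength_nm and reflectance")
    if (any(wall_reflectance$reflectance <= 0) ||
        any(wall_reflectance$reflectance >= 1))
      stop_field("wall_reflectance", "must lie in (0, 1)")
  } else stop_field("wall_reflectance", "must be a scalar or a table")
  geom <- structure(list(sphere_diameter = sphere_diameter,
                         wall_reflectance = wall_reflectance,
                         port_diameters = port_diameters,
                         detector_view_diameter = detector_view_diameter,
                         baffled = FALSE),
                    class = "sphere_geometry")
  if (port_fractions(geom)$f_total >= 0.2)
    stop_field("port_diameters", "total port area fraction must stay below 0.2")
  geom
}

# port areas as fractions of the total sphere surface (pi D^2)
port_fractions <- function(geom) {
  f <- geom$port_diameters^2 / (4 * geom$sphere_diameter^2)
  list(f_ports = f, f_total = sum(f), f_sample = unname(f["sample"]),
       f_view = geom$detector_view_diameter^2 / (4 * geom$sphere_diameter^2))
}

wall_reflectance_at <- function(geom, wavelength_nm) {
  rw <- geom$wall_reflectance
  if (is.numeric(rw)) return(rw)
  if (wavelength_nm < min(rw$wavelength_nm) ||
      wavelength_nm > max(rw$wavelength_nm))
    stop_field("wall_reflectance", "wavelength outside the reflectance table")
  approx(rw$wavelength_nm, rw$reflectance, xout = wavelength_nm)$y
}

#' Integrating-sphere gain (sphere multiplier)
#'
#' First-order radiation-exchange multiplier of a single sphere whose sample
#' port is closed by a surface of reflectance `sample_R`:
#' \deqn{M = 1 / (1 - \rho_w (1 - f) - R_s f_s)}
#' with wall reflectance \eqn{\rho_w}, total open-port area fraction \eqn{f}
#' and sample-port fraction \eqn{f_s}. `sample_R = 0` describes an open
#' sample port.
#'
#' @param geom a [sphere_geometry]
#' @param sample_R reflectance closing the sample port, fraction in \[0, 1\]
#' @param wavelength_nm wavelength at which a tabulated wall reflectance is
#'   evaluated; ignored for a flat coating
#' @return the sphere multiplier (>= 1)
#' @examples
#' sphere_gain(sphere_geometry(), sample_R = 0.5)
#' @export
sphere_gain <- function(geom, sample_R, wavelength_nm = 600) {
  if (!inherits(geom, "sphere_geometry"))
    stop_field("geom", "must be a sphere_geometry object")
  check_number(sample_R, "sample_R", lower = 0, upper = 1)
  pf <- port_fractions(geom)
  rho_w <- wall_reflectance_at(geom, wavelength_nm)
  den <- 1 - rho_w * (1 - pf$f_total) - sample_R * pf$f_sample
  if (den <= 0)
    stop("nonphysical sphere configuration: gain denominator <= 0",
         call. = FALSE)
  1 / den
}

#' Sphere-referred effective reflectance and transmittance
#'
#' Converts the true hemispherical reflectance and transmittance of the slab
#' into the signals the sphere measurement actually reports after the
#' calibration algebra. In the model, light entering the sphere through the
#' sample port produces a detector signal proportional to
#' \eqn{\Phi (\delta + M)} -- a direct-view term \eqn{\delta} (the fraction
#' of first-bounce light landing in the detector's viewed wall area) plus the
#' integrated sphere gain \eqn{M} -- while wall-first normalization beams see
#' the gain only. The normalization channels cancel the substitution change
#' in the gain, so the residual bias of the measured values is carried
#' entirely by the direct-view term:
#' \deqn{R_{eff} = R (\delta + M_R) M_{cal} / (M_R (\delta + M_{cal}))}
#' \deqn{T_{eff} = T (\delta + M_R) M_0 / (M_R (\delta + M_0))}
#' where \eqn{M_R}, \eqn{M_{cal}}, \eqn{M_0} are the gains with the sample
#' port closed by the sample, the calibration mirror, and left open. The map
#' is strictly increasing in both `true_R` and `true_T`. Lookup tables built
#' with the same geometry apply this map to every cell, which removes the
#' bias on inversion.
#'
#' @param true_R,true_T slab hemispherical reflectance and transmittance,
#'   fractions in \[0, 1\]
#' @param geom a [sphere_geometry]
#' @param direct_fraction direct-view term \eqn{\delta}; the default derives
#'   it from the detector's viewed wall area
#' @param rho_cal hemispherical reflectance of the calibration mirror
#' @param wavelength_nm wavelength for a tabulated wall reflectance
#' @return an object of class `effective_rt`: list with `R_eff`, `T_eff`,
#'   `multiplier_sample`, `multiplier_cal`
#' @examples
#' effective_rt(0.4, 0.3, sphere_geometry())
#' @export
effective_rt <- function(true_R, true_T, geom,
                         direct_fraction = NULL, rho_cal = 0.98,
                         wavelength_nm = 600) {
  check_number(true_R, "true_R", lower = 0, upper = 1)
  check_number(true_T, "true_T", lower = 0, upper = 1)
  check_number(rho_cal, "rho_cal", lower = 0, upper = 1, strict_lower = TRUE)
  if (is.null(direct_fraction)) direct_fraction <- port_fractions(geom)$f_view
  check_number(direct_fraction, "direct_fraction", lower = 0, upper = 1)
  M_R <- sphere_gain(geom, true_R, wavelength_nm)
  M_cal <- sphere_gain(geom, rho_cal, wavelength_nm)
  M_0 <- sphere_gain(geom, 0, wavelength_nm)
  d <- direct_fraction
  structure(list(
    R_eff = true_R * (d + M_R) * M_cal / (M_R * (d + M_cal)),
    T_eff = true_T * (d + M_R) * M_0 / (M_R * (d + M_0)),
    multiplier_sample = M_R, multiplier_cal = M_cal),
    class = "effective_rt")
}

#' @export
print.effective_rt <- function(x, ...) {
  cat(sprintf("Sphere-referred signals: R_eff = %.6f, T_eff = %.6f\n",
              x$R_eff, x$T_eff))
  cat(sprintf("  gains: sample %.3f, calibration %.3f\n",
              x$multiplier_sample, x$multiplier_cal))
  invisible(x)
}
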