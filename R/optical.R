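#' Optical properties of a homogeneous turbid slab
#'
#' Bundles the five quantities that define light transport through one
#' homogeneous plane-parallel sample at one wavelength: the absorption
#' coefficient \eqn{\mu_a}, the reduced scattering coefficient
#' \eqn{\mu_s' = \mu_s (1 - g)}, the scattering anisotropy \eqn{g} (mean
#' cosine of the single-scattering polar angle), the refractive index of the
#' sample and its thickness. Internally the Monte Carlo solver works with the
#' full scattering coefficient \eqn{\mu_s = \mu_s'/(1-g)} and an explicit
#' Henyey-Greenstein phase function, while lookup tables are indexed by
#' \eqn{(\mu_a, \mu_s')}.
#'
#' @param mu_a absorption coefficient, 1/mm (>= 0)
#' @param mu_s_prime reduced scattering coefficient, 1/mm (>= 0)
#' @param g scattering anisotropy, dimensionless, in (-1, 1)
#' @param n_sample refractive index of the sample (>= 1)
#' @param thickness_d slab thickness, mm (> 0)
#' @return an object of class `optical_properties`
#' @examples
#' optical_properties(mu_a = 0.02, mu_s_prime = 4, g = 0.75,
#'                    n_sample = 1.41, thickness_d = 2)
#' @export
optical_properties <- function(mu_a, mu_s_prime, g = 0.75, n_sample = 1.41,
                               thickness_d = 2) {
  check_number(mu_a, "mu_a", lower = 0)
  check_number(mu_s_prime, "mu_s_prime", lower = 0)
  check_number(g, "g", lower = -1, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(n_sample, "n_sample", lower = 1)
  check_number(thickness_d, "thickness_d", lower = 0, strict_lower = TRUE)
  structure(list(mu_a = mu_a, mu_s_prime = mu_s_prime, g = g,
                 n_sample = n_sample, thickness_d = thickness_d),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat("Optical properties of a homogeneous slab\n")
  cat(sprintf("  mu_a        = %g 1/mm\n", x$mu_a))
  cat(sprintf("  mu_s'       = %g 1/mm  (mu_s = %g 1/mm at g = %g)\n",
              x$mu_s_prime, x$mu_s_prime / (1 - x$g), x$g))
  cat(sprintf("  n           = %g\n", x$n_sample))
  cat(sprintf("  thickness d = %g mm\n", x$thickness_d))
  invisible(x)
}

#' Illumination beam and collection-port geometry
#'
#' Describes how the slab is illuminated and which exiting photons the
#' integrating sphere can collect. The default matches a sphere whose sample
#' port is 25 mm in diameter illuminated by a 5 mm beam at 8 degrees from the
#' surface normal; photons leaving a slab face farther than `port_radius`
#' from the beam axis miss the port and are counted as lost.
#'
#' @param incidence_deg beam incidence angle, degrees from the normal
#' @param beam_radius beam radius at the sample, mm; `0` gives a pencil beam
#' @param port_radius collection-port radius, mm (may be `Inf` to disable
#'   port-loss accounting, e.g. when comparing against slab-only solvers)
#' @param n_ambient refractive index of the surroundings
#' @param lateral_max radial distance, mm, at which a photon still inside the
#'   slab is abandoned as a lateral loss
#' @return an object of class `beam_geometry`
#' @export
beam_geometry <- function(incidence_deg = 8, beam_radius = 2.5,
                          port_radius = 12.5, n_ambient = 1,
                          lateral_max = 75) {
  check_number(incidence_deg, "incidence_deg", lower = 0, upper = 90,
               strict_upper = TRUE)
  check_number(beam_radius, "beam_radius", lower = 0)
  if (!identical(port_radius, Inf))
    check_number(port_radius, "port_radius", lower = 0, strict_lower = TRUE)
  if (beam_radius > port_radius)
    stop_field("beam_radius", "must not exceed port_radius")
  check_number(n_ambient, "n_ambient", lower = 1)
  if (!identical(lateral_max, Inf))
    check_number(lateral_max, "lateral_max", lower = 0, strict_lower = TRUE)
  structure(list(incidence_deg = incidence_deg, beam_radius = beam_radius,
                 port_radius = port_radius, n_ambient = n_ambient,
                 lateral_max = lateral_max),
            class = "beam_geometry")
}

#' Pencil-beam geometry at normal incidence
#'
#' Convenience constructor used when comparing the Monte Carlo solver with
#' deterministic slab solvers (adding-doubling, Beer-Lambert), which assume an
#' infinitely narrow beam at normal incidence and no collection aperture.
#'
#' @param n_ambient refractive index of the surroundings
#' @return a `beam_geometry`
#' @export
pencil_beam <- function(n_ambient = 1) {
  beam_geometry(incidence_deg = 0, beam_radius = 0, port_radius = Inf,
                n_ambient = n_ambient, lateral_max = Inf)
}
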