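#' Particle specification for Mie calculations
#'
#' Describes a population of spherical scatterers embedded in a transparent
#' matrix: mean diameter, optional normal spread of diameters, the refractive
#' indices of particle and medium (constant, or tabulated against wavelength),
#' and optionally the particle number density that links single-particle
#' cross-sections to the reduced scattering coefficient of the bulk.
#'
#' Indices may be given as a single number or as a two-column `data.frame`
#' (`wavelength_nm`, `n`); tabulated indices are interpolated linearly and
#' queries outside the table raise an error.
#'
#' @param diameter_mean mean particle diameter, nm (> 0)
#' @param diameter_sd standard deviation of the diameter, nm; 0 = monodisperse
#' @param n_particle particle refractive index (scalar or table)
#' @param n_medium matrix refractive index (scalar or table)
#' @param number_density particles per mm^3, or `NULL` if unknown
#' @return an object of class `particle_spec`
#' @examples
#' particle_spec()  # 800 nm zirconia spheres in a silicone matrix
#' @export
particle_spec <- function(diameter_mean = 800, diameter_sd = 0,
                          n_particle = 2.15, n_medium = 1.41,
                          number_density = NULL) {
  check_number(diameter_mean, "diameter_mean", lower = 0, strict_lower = TRUE)
  check_number(diameter_sd, "diameter_sd", lower = 0)
  check_index_arg(n_particle, "n_particle")
  check_index_arg(n_medium, "n_medium")
  if (!is.null(number_density))
    check_number(number_density, "number_density", lower = 0,
                 strict_lower = TRUE)
  structure(list(diameter_mean = diameter_mean, diameter_sd = diameter_sd,
                 n_particle = n_particle, n_medium = n_medium,
                 number_density = number_density),
            class = "particle_spec")
}

check_index_arg <- function(x, field) {
  if (is.numeric(x) && length(x) == 1L) {
    check_number(x, field, lower = 1)
  } else if (is.data.frame(x)) {
    if (!all(c("wavelength_nm", "n") %in% names(x)))
      stop_field(field, "table needs columns wavelength_nm and n")
    if (any(x$n < 1)) stop_field(field, "indices must be >= 1")
    if (is.unsorted(x$wavelength_nm, strictly = TRUE))
      stop_field(field, "wavelength_nm must be strictly ascending")
  } else stop_field(field, "must be a scalar index or a dispersion table")
  invisible(x)
}

index_at <- function(x, wavelength_nm, field) {
  if (is.numeric(x)) return(rep(x, length(wavelength_nm)))
  if (any(wavelength_nm < min(x$wavelength_nm)) ||
      any(wavelength_nm > max(x$wavelength_nm)))
    stop_field(field, "queried wavelength outside the dispersion table")
  approx(x$wavelength_nm, x$n, xout = wavelength_nm)$y
}

#' Mie efficiencies and asymmetry factor of a single sphere
#'
#' Computes the extinction and scattering efficiencies and the asymmetry
#' factor \eqn{g} (mean cosine of the scattering angle) of a homogeneous
#' sphere from Lorenz-Mie theory. The partial-wave series is truncated at the
#' Wiscombe order \eqn{x + 4 x^{1/3} + 2}; the logarithmic derivative of the
#' Riccati-Bessel function is obtained by downward recurrence, and the angular
#' moments entering \eqn{g} are evaluated analytically from the Mie
#' coefficients rather than by quadrature of the phase function.
#'
#' @param size_parameter size parameter \eqn{x = \pi D n_{med} / \lambda}
#' @param rel_index relative refractive index \eqn{m = n_p / n_{med}}, real
#'   and at least 1 (absorbing particles are out of scope)
#' @param n_extra additional series terms beyond the Wiscombe order, used to
#'   demonstrate truncation stability
#' @return an object of class `mie_result`: list with `q_ext`, `q_sca`,
#'   `g_factor`, `size_parameter`, `rel_index`
#' @examples
#' mie_single(5.213, 1.55)  # classic worked example, q_ext ~ 3.105
#' @export
mie_single <- function(size_parameter, rel_index, n_extra = 0) {
  check_number(size_parameter, "size_parameter", lower = 0,
               strict_lower = TRUE)
  check_number(rel_index, "rel_index", lower = 1)
  check_number(n_extra, "n_extra", lower = 0)
  x <- size_parameter
  m <- rel_index
  nstop <- ceiling(x + 4 * x^(1 / 3) + 2) + as.integer(n_extra)

  # logarithmic derivative D_n(mx) by downward recurrence
  nmx <- max(nstop, ceiling(abs(m * x))) + 16L
  D <- numeric(nmx + 1L)
  mx <- m * x
  # downward recurrence D_n = (n+1)/mx - 1/(D_{n+1} + (n+1)/mx); D[k] = D_k
  for (n in nmx:1) D[n] <- (n + 1) / mx - 1 / (D[n + 1L] + (n + 1) / mx)

  # Riccati-Bessel psi, chi by upward recurrence
  psi_m1 <- cos(x); psi_0 <- sin(x)
  chi_m1 <- -sin(x); chi_0 <- cos(x)
  a <- complex(nstop); b <- complex(nstop)
  psi_prev <- psi_m1; psi_cur <- psi_0
  chi_prev <- chi_m1; chi_cur <- chi_0
  for (n in seq_len(nstop)) {
    psi_n <- (2 * n - 1) / x * psi_cur - psi_prev
    chi_n <- (2 * n - 1) / x * chi_cur - chi_prev
    xi_n <- complex(real = psi_n, imaginary = -chi_n)
    xi_cur <- complex(real = psi_cur, imaginary = -chi_cur)
    ta <- D[n] / m + n / x
    tb <- D[n] * m + n / x
    a[n] <- (ta * psi_n - psi_cur) / (ta * xi_n - xi_cur)
    b[n] <- (tb * psi_n - psi_cur) / (tb * xi_n - xi_cur)
    psi_prev <- psi_cur; psi_cur <- psi_n
    chi_prev <- chi_cur; chi_cur <- chi_n
  }

  n <- seq_len(nstop)
  q_sca <- 2 / x^2 * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  q_ext <- 2 / x^2 * sum((2 * n + 1) * Re(a + b))
  gsum <- 0
  if (nstop >= 2) {
    k <- seq_len(nstop - 1L)
    gsum <- sum(k * (k + 2) / (k + 1) *
                  Re(a[k] * Conj(a[k + 1L]) + b[k] * Conj(b[k + 1L])))
  }
  gsum <- gsum + sum((2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b)))
  g <- if (q_sca > 0) 4 / (x^2 * q_sca) * gsum else 0

  structure(list(q_ext = q_ext, q_sca = q_sca, g_factor = g,
                 size_parameter = x, rel_index = m),
            class = "mie_result")
}

#' @export
print.mie_result <- function(x, ...) {
  cat(sprintf("Mie sphere: x = %.4g, m = %.4g\n", x$size_parameter,
              x$rel_index))
  cat(sprintf("  Q_ext = %.6f  Q_sca = %.6f  g = %.6f\n",
              x$q_ext, x$q_sca, x$g_factor))
  invisible(x)
}

# diameter quadrature nodes/weights for the (possibly degenerate) normal
# size distribution, truncated at +-3 sd, 21 nodes
size_distribution_nodes <- function(particle, n_nodes = 21L) {
  if (particle$diameter_sd <= 0)
    return(list(d = particle$diameter_mean, w = 1))
  z <- seq(-3, 3, length.out = n_nodes)
  d <- particle$diameter_mean + z * particle$diameter_sd
  keep <- d > 0
  w <- exp(-z[keep]^2 / 2)
  list(d = d[keep], w = w / sum(w))
}

#' Asymmetry-factor spectrum of a particle population
#'
#' Per-wavelength asymmetry factor \eqn{g(\lambda)} for the particle
#' population, with the size parameter referred to the wavelength in the
#' matrix (\eqn{x = \pi D n_{med}/\lambda}). For a polydisperse population the
#' per-diameter values are averaged with scattering-cross-section weights
#' \eqn{Q_{sca} D^2}, the physically relevant weighting for the bulk phase
#' function.
#'
#' @param particle a [particle_spec]
#' @param wavelengths vacuum wavelengths, nm (non-empty)
#' @return numeric vector of `g` values, one per wavelength
#' @examples
#' mean(g_spectrum(particle_spec(), seq(320, 1000, by = 10)))
#' @export
g_spectrum <- function(particle, wavelengths) {
  spectrum_over_sizes(particle, wavelengths)$g
}

#' Reduced scattering coefficient spectrum of a particle-loaded matrix
#'
#' \eqn{\mu_s'(\lambda) = N \sigma_{geom} Q_{sca} (1 - g)} with the particle
#' number density `N` (per mm^3) and the geometric cross-section
#' \eqn{\sigma_{geom} = \pi (D/2)^2} (in mm^2). For a polydisperse population
#' the product is averaged over the size distribution.
#'
#' @param particle a [particle_spec] with `number_density` set
#' @param wavelengths vacuum wavelengths, nm (non-empty)
#' @return numeric vector of reduced scattering coefficients, 1/mm
#' @export
musp_spectrum <- function(particle, wavelengths) {
  if (is.null(particle$number_density))
    stop_field("number_density", "must be set to compute mu_s'")
  spectrum_over_sizes(particle, wavelengths)$musp
}

spectrum_over_sizes <- function(particle, wavelengths) {
  if (!inherits(particle, "particle_spec"))
    stop_field("particle", "must be a particle_spec object")
  if (length(wavelengths) == 0)
    stop_field("wavelengths", "must be non-empty")
  nodes <- size_distribution_nodes(particle)
  n_med <- index_at(particle$n_medium, wavelengths, "n_medium")
  n_par <- index_at(particle$n_particle, wavelengths, "n_particle")
  g_out <- numeric(length(wavelengths))
  musp_out <- numeric(length(wavelengths))
  dens <- if (is.null(particle$number_density)) 0 else particle$number_density
  for (i in seq_along(wavelengths)) {
    m <- n_par[i] / n_med[i]
    g_num <- 0; g_den <- 0; musp_acc <- 0
    for (k in seq_along(nodes$d)) {
      d_nm <- nodes$d[k]
      x <- pi * d_nm * n_med[i] / wavelengths[i]
      mie <- mie_single(x, m)
      sigma_sca <- mie$q_sca * d_nm^2          # relative weight only
      g_num <- g_num + nodes$w[k] * sigma_sca * mie$g_factor
      g_den <- g_den + nodes$w[k] * sigma_sca
      sigma_geom_mm2 <- pi * (d_nm * 1e-6 / 2)^2
      musp_acc <- musp_acc + nodes$w[k] * dens * sigma_geom_mm2 *
        mie$q_sca * (1 - mie$g_factor)
    }
    g_out[i] <- if (g_den > 0) g_num / g_den else 0
    musp_out[i] <- musp_acc
  }
  list(g = g_out, musp = musp_out)
}
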