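# Independent oracles used by the test suite. Each is coded from first
# principles with a different algorithm than the package implementation, so
# agreement between the two routes is evidence for both.

# ---- Gauss / Gauss-Radau quadrature (Golub-Welsch with Jacobi matrices) ----

# Gauss-Legendre nodes/weights on [lo, hi]
oracle_gauss <- function(n, lo, hi) {
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- rev(e$values)
  w <- 2 * rev(e$vectors[1, ]^2)
  list(x = (x + 1) / 2 * (hi - lo) + lo, w = w / 2 * (hi - lo))
}

# Gauss-Radau on [lo, hi] with a prescribed node at the upper endpoint
oracle_radau_upper <- function(n, lo, hi) {
  stopifnot(n >= 2)
  # monic Legendre recurrence coefficients on [-1, 1]
  alpha <- rep(0, n)
  k <- seq_len(n - 1)
  beta <- c(2, k^2 / (4 * k^2 - 1)) # beta_0 = integral of weight
  # Gautschi's endpoint modification at t = +1
  t <- 1
  pim1 <- 0; pi0 <- 1 # monic pi_{-1}, pi_0 at t
  for (j in seq_len(n - 1)) {
    pinew <- (t - alpha[j]) * pi0 - (if (j >= 2) beta[j] else 0) * pim1
    pim1 <- pi0; pi0 <- pinew
  }
  alpha[n] <- t - beta[n] * pim1 / pi0
  offd <- sqrt(beta[2:n])
  J <- matrix(0, n, n)
  J[cbind(1:(n - 1), 2:n)] <- offd
  J[cbind(2:n, 1:(n - 1))] <- offd
  diag(J) <- alpha
  e <- eigen(J, symmetric = TRUE)
  x <- rev(e$values)
  w <- beta[1] * rev(e$vectors[1, ]^2)
  list(x = (x + 1) / 2 * (hi - lo) + lo, w = w / 2 * (hi - lo))
}

# ---- adding-doubling slab solver (van de Hulst doubling + Fresnel bounds) --

oracle_fresnel <- function(ni, nt, ci) {
  st2 <- (ni / nt)^2 * (1 - ci^2)
  if (st2 >= 1) return(1)
  ct <- sqrt(1 - st2)
  rs <- (ni * ci - nt * ct) / (ni * ci + nt * ct)
  rp <- (ni * ct - nt * ci) / (ni * ct + nt * ci)
  (rs^2 + rp^2) / 2
}

# azimuth-averaged Henyey-Greenstein redistribution matrix via the Legendre
# addition theorem: h(mu_i, mu_j) = sum (2l+1) g^l P_l(mu_i) P_l(mu_j)
oracle_hg_redistribution <- function(mu, g, lmax = 160) {
  n <- length(mu)
  P <- matrix(0, lmax + 1, n)
  P[1, ] <- 1
  if (lmax >= 1) P[2, ] <- mu
  for (l in 2:lmax)
    P[l + 1, ] <- ((2 * l - 1) * mu * P[l, ] - (l - 1) * P[l - 1, ]) / l
  hpp <- matrix(0, n, n); hpm <- matrix(0, n, n)
  for (l in 0:lmax) {
    cl <- (2 * l + 1) * g^l
    if (abs(cl) < 1e-14 && l > 2) break
    outer_l <- outer(P[l + 1, ], P[l + 1, ])
    hpp <- hpp + cl * outer_l
    hpm <- hpm + cl * (-1)^l * outer_l
  }
  list(hpp = hpp, hpm = hpm)
}

# Total hemispherical R and T of a homogeneous slab, collimated normal
# incidence, refractive index n against index-matched surroundings handled
# via Fresnel boundary operators in the internal-angle quadrature.
oracle_adding_doubling <- function(mua, musp, g, n_index, d, m_nodes = 24) {
  mus <- if (g != 0) musp / (1 - g) else musp
  tau <- (mua + mus) * d
  a <- if (mua + mus > 0) mus / (mua + mus) else 0

  if (n_index > 1) {
    mu_c <- sqrt(1 - 1 / n_index^2)
    q1 <- oracle_gauss(m_nodes %/% 2, 0, mu_c)
    q2 <- oracle_radau_upper(m_nodes - m_nodes %/% 2, mu_c, 1)
    mu <- c(q1$x, q2$x); w <- c(q1$w, q2$w)
  } else {
    q <- oracle_radau_upper(m_nodes, 0, 1)
    mu <- q$x; w <- q$w
  }
  M <- length(mu)
  iN <- which.max(mu) # the mu = 1 node carrying the collimated beam

  h <- oracle_hg_redistribution(mu, g)

  # thin-layer initialization in "hat" (radiance-operator) form
  n_doubling <- max(0, ceiling(log2(tau / 1e-6)))
  tau0 <- if (tau > 0) tau / 2^n_doubling else 0
  r <- a * tau0 / 2 * h$hpm * outer(1 / mu, w)
  tt <- a * tau0 / 2 * h$hpp * outer(1 / mu, w) + diag(1 - tau0 / mu)
  if (tau > 0) {
    for (k in seq_len(n_doubling)) {
      x <- solve(diag(M) - r %*% r)
      r_new <- r + tt %*% r %*% x %*% tt
      tt <- tt %*% x %*% tt
      r <- r_new
    }
  }

  # Fresnel boundary operators in the internal angle set
  rf <- vapply(mu, function(m) oracle_fresnel(n_index, 1, m), numeric(1))
  rho_b <- diag(rf)          # internal reflection at either face
  flux <- 2 * mu * w

  rs <- oracle_fresnel(1, n_index, 1) # specular entry reflection
  d_src <- numeric(M)
  d_src[iN] <- (1 - rs) / flux[iN]    # unit-flux collimated beam inside

  inv_bot <- solve(diag(M) - r %*% rho_b)
  r_sb <- r + tt %*% rho_b %*% inv_bot %*% tt # slab + bottom boundary
  d_vec <- solve(diag(M) - rho_b %*% r_sb, d_src)
  u_top <- r_sb %*% d_vec
  d_bot <- inv_bot %*% tt %*% d_vec

  R_total <- rs + sum(flux * (1 - rf) * u_top)
  T_total <- sum(flux * (1 - rf) * d_bot)
  list(R = R_total, T = T_total)
}

# ---- brute-force Mie via half-integer Bessel functions ---------------------

# Riccati-Bessel psi_n(x) = x j_n(x) and chi_n(x) = -x y_n(x) from base R
# Bessel functions; derivatives from the standard recurrence.
oracle_mie <- function(x, m, nmax = NULL) {
  if (is.null(nmax)) nmax <- ceiling(x + 4 * x^(1 / 3) + 10)
  n <- seq_len(nmax)
  sj <- function(nu, z) besselJ(z, nu + 0.5) * sqrt(pi / (2 * z))
  sy <- function(nu, z) besselY(z, nu + 0.5) * sqrt(pi / (2 * z))
  psi <- function(nu, z) z * sj(nu, z)
  chi <- function(nu, z) -z * sy(nu, z)
  psi_x <- psi(n, x); psi_xm1 <- psi(n - 1, x)
  psi_mx <- psi(n, m * x); psi_mxm1 <- psi(n - 1, m * x)
  chi_x <- chi(n, x); chi_xm1 <- chi(n - 1, x)
  dpsi_x <- psi_xm1 - n / x * psi_x
  dpsi_mx <- psi_mxm1 - n / (m * x) * psi_mx
  xi_x <- complex(real = psi_x, imaginary = -chi_x)
  dxi_x <- complex(real = dpsi_x, imaginary = -(chi_xm1 - n / x * chi_x))
  a <- (m * psi_mx * dpsi_x - psi_x * dpsi_mx) /
    (m * psi_mx * dxi_x - xi_x * dpsi_mx)
  b <- (psi_mx * dpsi_x - m * psi_x * dpsi_mx) /
    (psi_mx * dxi_x - m * xi_x * dpsi_mx)
  q_sca <- 2 / x^2 * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  q_ext <- 2 / x^2 * sum((2 * n + 1) * Re(a + b))
  k <- seq_len(nmax - 1)
  gsum <- sum(k * (k + 2) / (k + 1) *
                Re(a[k] * Conj(a[k + 1]) + b[k] * Conj(b[k + 1]))) +
    sum((2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b)))
  list(q_ext = q_ext, q_sca = q_sca, g = 4 / (x^2 * q_sca) * gsum)
}

# ---- few-patch radiosity model of the integrating sphere -------------------

# Discrete radiosity with explicit patches. On a sphere interior every patch
# sees every other with view factor proportional to area, which the solver
# does NOT assume: it builds the full view-factor matrix and solves the
# linear system, so the algebra is an independent check of the closed-form
# sphere gain.
oracle_sphere_radiosity <- function(geom, sample_R, injected_flux = 1,
                                    first_patch = "sample") {
  Ds <- geom$sphere_diameter
  A_tot <- pi * Ds^2
  ports <- geom$port_diameters
  A_ports <- pi * ports^2 / 4
  A_wall <- A_tot - sum(A_ports)
  areas <- c(wall = A_wall, sample = unname(A_ports["sample"]),
             reflection = unname(A_ports["reflection"]),
             normalization = unname(A_ports["normalization"]),
             detection = unname(A_ports["detection"]))
  rho <- c(wall = geom$wall_reflectance, sample = sample_R,
           reflection = 0, normalization = 0, detection = 0)
  np <- length(areas)
  FF <- matrix(rep(areas / A_tot, each = np), np, np) # F_ij = A_j / A_tot
  # direct irradiation: the injected flux first strikes `first_patch`
  E <- numeric(np); names(E) <- names(areas)
  E[first_patch] <- injected_flux / areas[first_patch]
  # B_i = rho_i (E_i + sum_j F_ij B_j)
  B <- solve(diag(np) - diag(rho) %*% FF, rho * E)
  names(B) <- names(areas)
  # wall radiosity per unit flux = what a detector viewing the wall reads
  list(B = B, irradiance = as.vector(FF %*% B))
}
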