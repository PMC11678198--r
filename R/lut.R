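#' Build a Monte Carlo lookup table R(mu_a, mu_s'), T(mu_a, mu_s')
#'
#' Runs the slab Monte Carlo on every node of a (mu_a, mu_s') grid for fixed
#' anisotropy, refractive index and thickness, and optionally maps each cell
#' through the integrating-sphere correction so the table lives in the same
#' (sphere-referred) units as the measured reflectance and transmittance.
#' Cell seeds are derived deterministically from `seed`, so a table is fully
#' reproducible from its metadata.
#'
#' @param mua_grid absorption grid, 1/mm, strictly ascending (log spacing
#'   recommended: mu_a spans decades)
#' @param musp_grid reduced-scattering grid, 1/mm, strictly ascending
#' @param fixed_params list with `g`, `n`, `d` (anisotropy, sample index,
#'   thickness in mm)
#' @param beam a [beam_geometry]
#' @param sphere a [sphere_geometry], or `NULL` for an uncorrected slab-only
#'   table
#' @param n_photons photon packets per cell (>= 1000)
#' @param seed base RNG seed
#' @param rho_cal,direct_fraction,wavelength_nm sphere-correction settings
#'   passed to [effective_rt()]
#' @return an object of class `lookup_table`
#' @seealso [invert_rt()], [write_lut()]
#' @export
build_lut <- function(mua_grid, musp_grid,
                      fixed_params = list(g = 0.75, n = 1.41, d = 2),
                      beam = beam_geometry(), sphere = NULL,
                      n_photons = 1e5, seed = 1,
                      rho_cal = 0.98, direct_fraction = NULL,
                      wavelength_nm = 600) {
  if (length(mua_grid) < 2 || is.unsorted(mua_grid, strictly = TRUE) ||
      any(mua_grid < 0))
    stop_field("mua_grid", "must be >= 0 and strictly ascending")
  if (length(musp_grid) < 2 || is.unsorted(musp_grid, strictly = TRUE) ||
      any(musp_grid < 0))
    stop_field("musp_grid", "must be >= 0 and strictly ascending")
  if (!all(c("g", "n", "d") %in% names(fixed_params)))
    stop_field("fixed_params", "needs entries g, n, d")
  check_number(n_photons, "n_photons", lower = 1000)

  na <- length(mua_grid); ns <- length(musp_grid)
  R_tab <- matrix(NA_real_, na, ns)
  T_tab <- matrix(NA_real_, na, ns)
  seR_tab <- matrix(NA_real_, na, ns)
  seT_tab <- matrix(NA_real_, na, ns)
  for (j in seq_len(ns)) {
    for (i in seq_len(na)) {
      props <- optical_properties(mua_grid[i], musp_grid[j],
                                  g = fixed_params$g, n_sample = fixed_params$n,
                                  thickness_d = fixed_params$d)
      cell_seed <- seed + (j - 1L) * na + (i - 1L)
      res <- simulate_rt(props, beam, n_photons = n_photons, seed = cell_seed)
      if (!is.null(sphere)) {
        eff <- effective_rt(res$R_total, res$T_total, sphere,
                            direct_fraction = direct_fraction,
                            rho_cal = rho_cal, wavelength_nm = wavelength_nm)
        scale_R <- if (res$R_total > 0) eff$R_eff / res$R_total else 1
        scale_T <- if (res$T_total > 0) eff$T_eff / res$T_total else 1
        R_tab[i, j] <- eff$R_eff; T_tab[i, j] <- eff$T_eff
        seR_tab[i, j] <- res$se_R * scale_R
        seT_tab[i, j] <- res$se_T * scale_T
      } else {
        R_tab[i, j] <- res$R_total; T_tab[i, j] <- res$T_total
        seR_tab[i, j] <- res$se_R; seT_tab[i, j] <- res$se_T
      }
    }
  }
  structure(list(mua_grid = mua_grid, musp_grid = musp_grid,
                 R_table = R_tab, T_table = T_tab,
                 seR_table = seR_tab, seT_table = seT_tab,
                 fixed_params = fixed_params[c("g", "n", "d")],
                 sphere_meta = if (is.null(sphere)) "none" else sphere,
                 rho_cal = rho_cal,
                 direct_fraction = direct_fraction,
                 mc_meta = list(n_photons = n_photons, seed = seed,
                                beam = beam)),
            class = "lookup_table")
}

#' @export
print.lookup_table <- function(x, ...) {
  cat(sprintf("Lookup table %d x %d (mu_a x mu_s')\n",
              length(x$mua_grid), length(x$musp_grid)))
  cat(sprintf("  mu_a  in [%g, %g] 1/mm; mu_s' in [%g, %g] 1/mm\n",
              min(x$mua_grid), max(x$mua_grid),
              min(x$musp_grid), max(x$musp_grid)))
  cat(sprintf("  fixed: g = %g, n = %g, d = %g mm; sphere correction: %s\n",
              x$fixed_params$g, x$fixed_params$n, x$fixed_params$d,
              if (identical(x$sphere_meta, "none")) "none" else "applied"))
  cat(sprintf("  %g photons/cell, base seed %g\n",
              x$mc_meta$n_photons, x$mc_meta$seed))
  invisible(x)
}

# bilinear value and gradient of both tables at (mua, musp)
lut_interp <- function(lut, mua, musp) {
  ga <- lut$mua_grid; gs <- lut$musp_grid
  i <- findInterval(mua, ga, rightmost.closed = TRUE)
  j <- findInterval(musp, gs, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(ga) - 1L)
  j <- min(max(j, 1L), length(gs) - 1L)
  da <- ga[i + 1L] - ga[i]; ds <- gs[j + 1L] - gs[j]
  u <- (mua - ga[i]) / da; v <- (musp - gs[j]) / ds
  bil <- function(M) {
    m11 <- M[i, j]; m21 <- M[i + 1L, j]
    m12 <- M[i, j + 1L]; m22 <- M[i + 1L, j + 1L]
    val <- (1 - u) * (1 - v) * m11 + u * (1 - v) * m21 +
      (1 - u) * v * m12 + u * v * m22
    dda <- ((1 - v) * (m21 - m11) + v * (m22 - m12)) / da
    dds <- ((1 - u) * (m12 - m11) + u * (m22 - m21)) / ds
    c(val, dda, dds)
  }
  r <- bil(lut$R_table); t <- bil(lut$T_table)
  list(R = r[1], T = t[1], dR = r[2:3], dT = t[2:3])
}

# ray-casting point-in-polygon test (polygon as two-column matrix)
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  jj <- n
  for (ii in seq_len(n)) {
    xi <- poly[ii, 1]; yi <- poly[ii, 2]
    xj <- poly[jj, 1]; yj <- poly[jj, 2]
    if (((yi > py) != (yj > py)) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)) inside <- !inside
    jj <- ii
  }
  inside
}

#' Invert measured (R, T) to optical properties
#'
#' Two-dimensional inversion of a measured reflectance/transmittance pair
#' against a lookup table: the grid node closest in (R, T) Euclidean distance
#' seeds damped Gauss-Newton refinement on the bilinear interpolant, with the
#' parameters clamped to the grid hull. Measurements outside the convex hull
#' of the tabulated (R, T) values are flagged `extrapolated` and answered
#' with the nearest-boundary estimate rather than silently. When two
#' well-separated grid minima have residuals within `1e-4` of each other the
#' result is flagged `ambiguous`.
#'
#' The determinant of the Jacobian of (R, T) with respect to
#' \eqn{(\log \mu_a, \mu_s')} at the solution is returned; values below
#' `jacobian_floor` add a `flat-jacobian` flag (inversion poorly conditioned,
#' typical at extreme albedo where the forward map flattens).
#'
#' @param R_meas,T_meas measured (sphere-referred) reflectance and
#'   transmittance
#' @param lut a [build_lut()] table
#' @param jacobian_floor conditioning floor for `|det J|`
#' @return an object of class `inversion_result`: list with `mu_a`,
#'   `mu_s_prime`, `residual` (Euclidean distance in (R, T)), `flags`,
#'   `det_jacobian`
#' @examples
#' \donttest{
#' lut <- build_lut(c(0.01, 0.1, 0.5), c(1, 4, 8), n_photons = 1e3)
#' invert_rt(lut$R_table[2, 2], lut$T_table[2, 2], lut)
#' }
#' @export
invert_rt <- function(R_meas, T_meas, lut, jacobian_floor = 1e-6) {
  if (!inherits(lut, "lookup_table"))
    stop_field("lut", "must be a lookup_table object")
  check_number(R_meas, "R_meas", lower = 0)
  check_number(T_meas, "T_meas", lower = 0)

  ga <- lut$mua_grid; gs <- lut$musp_grid
  na <- length(ga); ns <- length(gs)
  d2 <- (lut$R_table - R_meas)^2 + (lut$T_table - T_meas)^2
  best <- arrayInd(which.min(d2), dim(d2))
  flags <- character(0)

  # ambiguity: second-best local node minimum far from the best one
  ord <- order(d2)
  best_d <- sqrt(d2[ord[1]])
  for (k in ord[-1]) {
    idx <- arrayInd(k, dim(d2))
    if (abs(idx[1] - best[1]) > 1 || abs(idx[2] - best[2]) > 1) {
      if (sqrt(d2[k]) - best_d < 1e-4) flags <- c(flags, "ambiguous")
      break
    }
  }

  # convex-hull membership of the measurement in (R, T) space
  pts <- cbind(as.vector(lut$R_table), as.vector(lut$T_table))
  hull <- grDevices::chull(pts)
  if (!point_in_polygon(R_meas, T_meas, pts[hull, , drop = FALSE]))
    flags <- c(flags, "extrapolated")

  # damped Gauss-Newton on the bilinear interpolant, clamped to the grid
  a <- ga[best[1]]; s <- gs[best[2]]
  for (iter in seq_len(60)) {
    ip <- lut_interp(lut, a, s)
    r <- c(ip$R - R_meas, ip$T - T_meas)
    J <- rbind(ip$dR, ip$dT)
    JtJ <- crossprod(J) + diag(1e-12, 2)
    step <- tryCatch(solve(JtJ, crossprod(J, -r)),
                     error = function(e) c(0, 0))
    lambda <- 1
    f0 <- sum(r^2)
    repeat {
      a_new <- min(max(a + lambda * step[1], ga[1]), ga[na])
      s_new <- min(max(s + lambda * step[2], gs[1]), gs[ns])
      ipn <- lut_interp(lut, a_new, s_new)
      if (sum(c(ipn$R - R_meas, ipn$T - T_meas)^2) <= f0 || lambda < 1e-6)
        break
      lambda <- lambda / 2
    }
    moved <- abs(a_new - a) + abs(s_new - s)
    a <- a_new; s <- s_new
    if (moved < 1e-12) break
  }
  ip <- lut_interp(lut, a, s)
  residual <- sqrt((ip$R - R_meas)^2 + (ip$T - T_meas)^2)

  # |det J| of (R, T) w.r.t. (log mu_a, mu_s')
  J <- rbind(c(ip$dR[1] * a, ip$dR[2]), c(ip$dT[1] * a, ip$dT[2]))
  detJ <- abs(det(J))
  if (detJ < jacobian_floor) flags <- c(flags, "flat-jacobian")
  if (!("extrapolated" %in% flags)) flags <- c(flags, "in-grid")

  structure(list(mu_a = a, mu_s_prime = s, residual = residual,
                 flags = flags, det_jacobian = detJ),
            class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf("Inversion: mu_a = %.5g 1/mm, mu_s' = %.5g 1/mm\n",
              x$mu_a, x$mu_s_prime))
  cat(sprintf("  residual %.3g in (R, T); flags: %s\n", x$residual,
              paste(x$flags, collapse = ", ")))
  invisible(x)
}

#' Invert a reflectance/transmittance spectrum wavelength by wavelength
#'
#' @param rt an `rt_spectrum` (see [compute_rt()]) or a `data.frame` with
#'   columns `wavelength`, `R`, `T`
#' @param lut a single [build_lut()] table used at every wavelength, or a
#'   named list of tables keyed by wavelength (names = nm)
#' @return a `data.frame` with columns `wavelength`, `mu_a`, `mu_s_prime`,
#'   `residual`, `flags` (comma-separated). Failures at single wavelengths
#'   are recorded in `flags` as `failed`, never fatal.
#' @export
invert_spectrum <- function(rt, lut) {
  df <- as.data.frame(unclass(rt)[c("wavelength", "R", "T")])
  pick_lut <- function(wl) {
    if (inherits(lut, "lookup_table")) return(lut)
    key <- as.character(wl)
    if (!key %in% names(lut))
      stop(sprintf("no lookup table for wavelength %s nm", key), call. = FALSE)
    lut[[key]]
  }
  out <- lapply(seq_len(nrow(df)), function(k) {
    res <- tryCatch(invert_rt(df$R[k], df$T[k], pick_lut(df$wavelength[k])),
                    error = function(e) NULL)
    if (is.null(res))
      return(data.frame(wavelength = df$wavelength[k], mu_a = NA_real_,
                        mu_s_prime = NA_real_, residual = NA_real_,
                        flags = "failed"))
    data.frame(wavelength = df$wavelength[k], mu_a = res$mu_a,
               mu_s_prime = res$mu_s_prime, residual = res$residual,
               flags = paste(res$flags, collapse = ","))
  })
  do.call(rbind, out)
}
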