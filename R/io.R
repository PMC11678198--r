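#' Write a spectral scan as delimited text
#'
#' Long-format tab-separated text with a commented header block carrying the
#' acquisition metadata: channel, number of averages, acquisition-time
#' schedule, and the dark-rate spectrum. `read_scan(write_scan(x))` restores
#' every field.
#'
#' @param scan a [spectral_scan]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_scan <- function(scan, path) {
  if (!inherits(scan, "spectral_scan"))
    stop_field("scan", "must be a spectral_scan")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# lumisphere spectral scan v1",
    paste0("# channel_id: ", scan$channel_id),
    paste0("# n_averages: ", format(scan$n_averages, digits = 17)),
    paste0("# preprocessed: ", scan$preprocessed),
    paste0("# acquisition_time_s: ",
           paste(format(scan$acquisition_time, digits = 17), collapse = ",")),
    paste0("# dark_rate: ",
           paste(format(scan$dark_spectrum, digits = 17), collapse = ","))),
    con)
  df <- data.frame(
    channel = scan$channel_id,
    excitation_nm = rep(scan$excitation_grid,
                        times = length(scan$emission_grid)),
    emission_nm = rep(scan$emission_grid,
                      each = length(scan$excitation_grid)),
    counts = as.vector(scan$counts))
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_header_field <- function(lines, key, path) {
  pat <- paste0("^# ", key, ": ")
  hit <- grep(pat, lines, value = TRUE)
  if (length(hit) != 1L)
    stop(sprintf("%s: missing or duplicated header field '%s'", path, key),
         call. = FALSE)
  sub(pat, "", hit)
}

#' Read a spectral scan written by [write_scan()]
#'
#' @param path file path
#' @return a [spectral_scan]
#' @export
read_scan <- function(path) {
  if (!file.exists(path)) stop(paste(path, "does not exist"), call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "# lumisphere spectral scan v1")
    stop(paste(path, "is not a lumisphere scan file"), call. = FALSE)
  n_header <- sum(startsWith(lines, "#"))
  if (length(lines) <= n_header + 1L)
    stop(paste(path, "contains no data rows"), call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  need <- c("channel", "excitation_nm", "emission_nm", "counts")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: expected columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  bad <- which(!is.finite(df$counts))
  if (length(bad) > 0)
    stop(sprintf("%s: malformed counts at data row %d", path, bad[1]),
         call. = FALSE)
  exc <- sort(unique(df$excitation_nm))
  em <- sort(unique(df$emission_nm))
  counts <- matrix(NA_real_, length(exc), length(em))
  counts[cbind(match(df$excitation_nm, exc), match(df$emission_nm, em))] <-
    df$counts
  if (any(is.na(counts)))
    stop(paste(path, "does not contain a complete excitation x emission grid"),
         call. = FALSE)
  acq <- as.numeric(strsplit(read_header_field(lines, "acquisition_time_s",
                                               path), ",")[[1]])
  if (any(!is.finite(acq)) || any(acq <= 0))
    stop(paste(path, "has a non-positive acquisition time"), call. = FALSE)
  dark <- as.numeric(strsplit(read_header_field(lines, "dark_rate", path),
                              ",")[[1]])
  scan <- spectral_scan(
    channel_id = read_header_field(lines, "channel_id", path),
    excitation_grid = exc, emission_grid = em, counts = counts,
    acquisition_time = acq,
    n_averages = as.numeric(read_header_field(lines, "n_averages", path)),
    dark_spectrum = dark)
  scan$preprocessed <- as.logical(read_header_field(lines, "preprocessed",
                                                    path))
  scan
}

#' Write a lookup table as structured text
#'
#' A plain-text container: a commented header with the version, fixed
#' parameters, Monte Carlo metadata and sphere-correction settings, followed
#' by one tab-separated row per grid cell (`mu_a`, `mu_s'`, `R`, `T`,
#' `se_R`, `se_T`). Diffable, and `read_lut()` restores the table
#' bit-exactly through the full-precision number formatting.
#'
#' @param lut a [build_lut()] table
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_lut <- function(lut, path) {
  if (!inherits(lut, "lookup_table"))
    stop_field("lut", "must be a lookup_table")
  con <- file(path, "w")
  on.exit(close(con))
  if (!identical(lut$sphere_meta, "none") &&
      !is.numeric(lut$sphere_meta$wall_reflectance))
    stop("lookup tables with a tabulated wall reflectance cannot be serialized; rebuild with the scalar reflectance at the table's wavelength",
         call. = FALSE)
  sph <- if (identical(lut$sphere_meta, "none")) "none" else
    paste(format(c(lut$sphere_meta$sphere_diameter,
                   lut$sphere_meta$port_diameters,
                   lut$sphere_meta$detector_view_diameter,
                   lut$sphere_meta$wall_reflectance),
                 digits = 17), collapse = ",")
  beam <- lut$mc_meta$beam
  writeLines(c(
    "# lumisphere lookup table v1",
    paste0("# g: ", format(lut$fixed_params$g, digits = 17)),
    paste0("# n: ", format(lut$fixed_params$n, digits = 17)),
    paste0("# d: ", format(lut$fixed_params$d, digits = 17)),
    paste0("# n_photons: ", format(lut$mc_meta$n_photons, digits = 17)),
    paste0("# seed: ", format(lut$mc_meta$seed, digits = 17)),
    paste0("# beam: ", paste(format(c(beam$incidence_deg, beam$beam_radius,
                                      beam$port_radius, beam$n_ambient,
                                      beam$lateral_max), digits = 17),
                             collapse = ",")),
    paste0("# sphere: ", sph),
    paste0("# rho_cal: ", format(lut$rho_cal, digits = 17)),
    paste0("# direct_fraction: ",
           if (is.null(lut$direct_fraction)) "default" else
             format(lut$direct_fraction, digits = 17)),
    paste0("# cells: ", length(lut$mua_grid) * length(lut$musp_grid))),
    con)
  grid <- expand.grid(i = seq_along(lut$mua_grid),
                      j = seq_along(lut$musp_grid))
  df <- data.frame(mua = lut$mua_grid[grid$i], musp = lut$musp_grid[grid$j],
                   R = lut$R_table[cbind(grid$i, grid$j)],
                   T = lut$T_table[cbind(grid$i, grid$j)],
                   se_R = lut$seR_table[cbind(grid$i, grid$j)],
                   se_T = lut$seT_table[cbind(grid$i, grid$j)])
  num <- vapply(df, function(col) format(col, digits = 17),
                matrix("", nrow(df), 1)[, 1])
  writeLines(paste(c("mua", "musp", "R", "T", "se_R", "se_T"),
                   collapse = "\t"), con)
  writeLines(apply(num, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a lookup table written by [write_lut()]
#'
#' @param path file path
#' @return a [build_lut()]-style `lookup_table`
#' @export
read_lut <- function(path) {
  if (!file.exists(path)) stop(paste(path, "does not exist"), call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "# lumisphere lookup table v1")
    stop(paste(path, "is not a lumisphere lookup table (version mismatch?)"),
         call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  n_cells <- as.integer(read_header_field(lines, "cells", path))
  mua_grid <- sort(unique(df$mua)); musp_grid <- sort(unique(df$musp))
  if (nrow(df) != n_cells ||
      nrow(df) != length(mua_grid) * length(musp_grid))
    stop(paste(path, "is truncated: incomplete grid"), call. = FALSE)
  idx <- cbind(match(df$mua, mua_grid), match(df$musp, musp_grid))
  mk <- function(col) {
    m <- matrix(NA_real_, length(mua_grid), length(musp_grid))
    m[idx] <- col
    if (any(is.na(m)))
      stop(paste(path, "is truncated: missing cells"), call. = FALSE)
    m
  }
  hf <- function(key) read_header_field(lines, key, path)
  beam_v <- as.numeric(strsplit(hf("beam"), ",")[[1]])
  sph_raw <- hf("sphere")
  sphere <- if (identical(sph_raw, "none")) "none" else {
    v <- as.numeric(strsplit(sph_raw, ",")[[1]])
    sphere_geometry(sphere_diameter = v[1],
                    port_diameters = c(sample = v[2], reflection = v[3],
                                       normalization = v[4],
                                       detection = v[5]),
                    detector_view_diameter = v[6],
                    wall_reflectance = v[7])
  }
  dfrac <- hf("direct_fraction")
  structure(list(
    mua_grid = mua_grid, musp_grid = musp_grid,
    R_table = mk(df$R), T_table = mk(df$T),
    seR_table = mk(df$se_R), seT_table = mk(df$se_T),
    fixed_params = list(g = as.numeric(hf("g")), n = as.numeric(hf("n")),
                        d = as.numeric(hf("d"))),
    sphere_meta = sphere,
    rho_cal = as.numeric(hf("rho_cal")),
    direct_fraction = if (identical(dfrac, "default")) NULL
                      else as.numeric(dfrac),
    mc_meta = list(n_photons = as.numeric(hf("n_photons")),
                   seed = as.numeric(hf("seed")),
                   beam = beam_geometry(incidence_deg = beam_v[1],
                                        beam_radius = beam_v[2],
                                        port_radius = beam_v[3],
                                        n_ambient = beam_v[4],
                                        lateral_max = beam_v[5]))),
    class = "lookup_table")
}

#' Read a run configuration from YAML
#'
#' Schema-checked configuration with blocks `sphere`, `phantom`, `lut`,
#' `processing`; unknown keys anywhere are rejected so typos fail loudly
#' before any computation starts.
#'
#' @param path YAML file path
#' @return list with validated `sphere` ([sphere_geometry]), `phantom`
#'   ([phantom_truth]), `lut` and `processing` blocks
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known_top <- c("sphere", "phantom", "lut", "processing")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown) > 0)
    stop(sprintf("%s: unknown config block(s): %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  take <- function(block, allowed) {
    x <- cfg[[block]]
    if (is.null(x)) return(list())
    extra <- setdiff(names(x), allowed)
    if (length(extra) > 0)
      stop(sprintf("%s: unknown key(s) in '%s': %s", path, block,
                   paste(extra, collapse = ", ")), call. = FALSE)
    x
  }
  sph <- take("sphere", c("sphere_diameter", "wall_reflectance",
                          "port_diameters", "detector_view_diameter"))
  if (!is.null(sph$port_diameters)) sph$port_diameters <-
    unlist(sph$port_diameters)
  ph <- take("phantom", names(formals(phantom_truth)))
  lut <- take("lut", c("mua_min", "mua_max", "n_mua", "musp_min", "musp_max",
                       "n_musp", "n_photons", "seed"))
  proc <- take("processing", c("window_nm", "mode", "rho_cal"))
  list(sphere = do.call(sphere_geometry, sph),
       phantom = do.call(phantom_truth, ph),
       lut = lut, processing = proc)
}

#' Grid helper: log-spaced absorption axis
#'
#' The absorption coefficient of real samples spans several decades
#' (roughly 2e-3 to 2e-1 1/mm in the validation batch), so the lookup-table
#' absorption axis is log-spaced by default while the scattering axis stays
#' linear.
#'
#' @param from,to range, 1/mm
#' @param n number of nodes
#' @return strictly ascending grid
#' @export
log_mua_grid <- function(from = 1e-4, to = 1, n = 40) {
  exp(seq(log(from), log(to), length.out = n))
}
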