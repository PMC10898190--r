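#' Default optical-property grids for the reflectance lookup table
#'
#' The absorption grid spans 0 and 1e-3 to 80 cm^-1 (log-spaced), and the
#' reduced-scattering grid 1 to 30 cm^-1, so that power-law scattering
#' spectra with amplitudes up to ~14 cm^-1 and powers up to ~2, and
#' absorption spectra up to the strongest observed methylene blue bands,
#' stay inside the table over the 450-750 nm range.
#'
#' @param n Number of (positive) nodes.
#' @name lut_grids
#' @export
default_mua_grid <- function(n = 44) {
  c(0, 10^seq(log10(1e-3), log10(80), length.out = n))
}

#' @rdname lut_grids
#' @export
default_musp_grid <- function(n = 26) {
  10^seq(log10(1), log10(30), length.out = n)
}

#' Build the spatially resolved reflectance lookup table
#'
#' Runs one white (zero-absorption) Monte Carlo simulation per reduced
#' scattering node and rescales its exit-path records across the absorption
#' grid, producing per-(mua, musp, separation) diffuse reflectance for the
#' probe.  Provenance (geometry, settings, seed) is embedded.
#'
#' Each scattering node uses its own deterministic seed derived from
#' `settings$seed`, so rebuilding with identical settings yields an
#' identical table.
#'
#' @param musp_grid,mua_grid Strictly increasing grids, cm^-1.
#' @param geometry A [probe_geometry()].
#' @param settings An [mc_settings()].
#' @return Object of class `reflectance_lut`.
#' @export
build_lut <- function(musp_grid = default_musp_grid(),
                      mua_grid = default_mua_grid(),
                      geometry = probe_geometry(),
                      settings = mc_settings()) {
  if (any(diff(mua_grid) <= 0) || any(diff(musp_grid) <= 0)) {
    stop("grids must be strictly increasing", call. = FALSE)
  }
  if (any(mua_grid < 0) || any(musp_grid <= 0)) {
    stop("nonphysical grid values", call. = FALSE)
  }
  nd <- length(geometry$separations_cm)
  refl <- array(NA_real_,
                c(length(mua_grid), length(musp_grid), nd),
                dimnames = list(NULL, NULL,
                                paste0("sep", seq_len(nd))))
  for (j in seq_along(musp_grid)) {
    st <- settings
    st$seed <- settings$seed + j - 1L
    run <- run_photon_mc(0, musp_grid[j], geometry, st, record_paths = TRUE)
    prep <- prepare_rescale(run$records)
    refl[, j, ] <- rescale_white_mc(prep, mua_grid)
  }
  structure(list(mua_grid = mua_grid, musp_grid = musp_grid,
                 reflectance = refl, geometry = geometry,
                 settings = settings,
                 # offset for the log-absorption interpolation coordinate;
                 # keeps mua = 0 representable and is log-like above ~0.1
                 u0 = 0.01),
            class = "reflectance_lut")
}

#' @export
print.reflectance_lut <- function(x, ...) {
  cat("Reflectance lookup table\n")
  cat(sprintf("  mua : %d nodes, %.3g-%.3g cm^-1\n", length(x$mua_grid),
              min(x$mua_grid), max(x$mua_grid)))
  cat(sprintf("  musp: %d nodes, %.3g-%.3g cm^-1\n", length(x$musp_grid),
              min(x$musp_grid), max(x$musp_grid)))
  cat(sprintf("  %d separations, %d photons/node, seed %d\n",
              length(x$geometry$separations_cm), x$settings$n_photons,
              x$settings$seed))
  invisible(x)
}

#' Interpolate lookup-table reflectance
#'
#' Bilinear interpolation of log-reflectance in transformed coordinates
#' `(log(mua + u0), log(musp))`; exact at grid nodes.  Queries outside the
#' grid hull raise an error of class `drsfit_out_of_range` (no silent
#' extrapolation).
#'
#' @param lut A [build_lut()] table.
#' @param mua,musp Query optical properties (cm^-1); vectors are recycled to
#'   common length.
#' @param separation Index of the detector separation (1-based), or a
#'   separation in cm matching one stored in the geometry.
#' @return Reflectance values (dimensionless per-fiber collected fraction).
#' @export
lut_reflectance <- function(lut, mua, musp, separation) {
  stopifnot(inherits(lut, "reflectance_lut"))
  k <- match_separation(lut, separation)
  n <- max(length(mua), length(musp))
  mua <- rep_len(mua, n); musp <- rep_len(musp, n)
  bad <- mua < min(lut$mua_grid) - 1e-12 | mua > max(lut$mua_grid) + 1e-12 |
    musp < min(lut$musp_grid) * (1 - 1e-12) |
    musp > max(lut$musp_grid) * (1 + 1e-12)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(errorCondition(
      sprintf("query outside LUT hull: mua = %.4g, musp = %.4g cm^-1",
              mua[i], musp[i]),
      class = "drsfit_out_of_range"))
  }
  u <- log(pmin(pmax(mua, min(lut$mua_grid)), max(lut$mua_grid)) + lut$u0)
  v <- log(pmin(pmax(musp, min(lut$musp_grid)), max(lut$musp_grid)))
  ug <- log(lut$mua_grid + lut$u0)
  vg <- log(lut$musp_grid)
  iu <- pmin(pmax(findInterval(u, ug), 1L), length(ug) - 1L)
  iv <- pmin(pmax(findInterval(v, vg), 1L), length(vg) - 1L)
  tu <- (u - ug[iu]) / (ug[iu + 1L] - ug[iu])
  tv <- (v - vg[iv]) / (vg[iv + 1L] - vg[iv])
  R <- lut$reflectance[, , k]
  # log-reflectance interpolation; floor avoids log(0) at rare empty nodes
  f <- function(i, j) log(pmax(R[cbind(i, j)], 1e-300))
  z <- (1 - tu) * (1 - tv) * f(iu, iv) + tu * (1 - tv) * f(iu + 1L, iv) +
    (1 - tu) * tv * f(iu, iv + 1L) + tu * tv * f(iu + 1L, iv + 1L)
  exp(z)
}

match_separation <- function(lut, separation) {
  nd <- length(lut$geometry$separations_cm)
  if (length(separation) != 1L) stop("one separation at a time", call. = FALSE)
  if (separation %in% seq_len(nd)) return(as.integer(separation))
  k <- which(abs(lut$geometry$separations_cm - separation) < 1e-9)
  if (length(k) != 1L) {
    stop("separation does not match a stored detector", call. = FALSE)
  }
  k
}

#' Save or load a reflectance lookup table
#'
#' Tables are persisted as self-describing JSON (grids, reflectance array,
#' geometry, transport settings and seed), portable and diff-able.
#'
#' @param lut A `reflectance_lut`.
#' @param path File path.
#' @return `read_lut` returns the restored `reflectance_lut`.
#' @export
write_lut <- function(lut, path) {
  obj <- list(mua_grid = lut$mua_grid, musp_grid = lut$musp_grid,
              reflectance = as.numeric(lut$reflectance),
              dim = dim(lut$reflectance),
              geometry = unclass(lut$geometry),
              settings = unclass(lut$settings), u0 = lut$u0)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  refl <- array(obj$reflectance, dim = obj$dim)
  dimnames(refl) <- list(NULL, NULL, paste0("sep", seq_len(obj$dim[3])))
  geometry <- structure(obj$geometry, class = "probe_geometry")
  settings <- structure(obj$settings, class = "mc_settings")
  structure(list(mua_grid = obj$mua_grid, musp_grid = obj$musp_grid,
                 reflectance = refl, geometry = geometry,
                 settings = settings, u0 = obj$u0),
            class = "reflectance_lut")
}
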