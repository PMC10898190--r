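#' Contact-probe geometry
#'
#' Describes the multi-fiber surface-contact probe: one source fiber and a
#' set of detector fibers at fixed center-to-center separations.  The default
#' is eight 200 um diameter fibers with separations evenly spaced from 320
#' to 1310 um (only the endpoint separations are published; the interior
#' positions are instrument-specific and should be supplied from probe
#' metrology when available).
#'
#' @param separations_um Strictly increasing detector separations, um.
#' @param fiber_radius_um Fiber core radius, um (source and detectors).
#' @param na Numerical aperture of the fibers.
#' @param n_fiber Refractive index of the probe face in contact with tissue.
#' @return Object of class `probe_geometry` (lengths internally in cm).
#' @export
probe_geometry <- function(separations_um = seq(320, 1310, length.out = 8),
                           fiber_radius_um = 100, na = 0.22, n_fiber = 1.45) {
  if (any(diff(separations_um) <= 0)) {
    stop("separations must be strictly increasing", call. = FALSE)
  }
  if (fiber_radius_um <= 0) stop("fiber radius must be positive", call. = FALSE)
  structure(list(separations_cm = separations_um * 1e-4,
                 fiber_radius_cm = fiber_radius_um * 1e-4,
                 na = na, n_fiber = n_fiber),
            class = "probe_geometry")
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat("Contact probe:", length(x$separations_cm), "detector fibers,",
      sprintf("separations %g-%g um, radius %g um, NA %g, n_face %g\n",
              1e4 * min(x$separations_cm), 1e4 * max(x$separations_cm),
              1e4 * x$fiber_radius_cm, x$na, x$n_fiber))
  invisible(x)
}

#' Monte Carlo transport settings
#'
#' @param n_photons Photons per run (>= 1e4 recommended for production
#'   lookup tables).
#' @param seed Integer seed for the kernel's own deterministic RNG stream
#'   (independent of R's global RNG state).
#' @param g Henyey-Greenstein anisotropy, in `[0, 1)`.
#' @param n_tissue Tissue refractive index.
#' @param w_min Roulette weight threshold.
#' @param p_roulette Roulette survival probability.
#' @param max_path_cm Path-length cap (cm); needed because the exit-path
#'   distribution of a non-absorbing half-space is heavy tailed.
#' @return Object of class `mc_settings`.
#' @export
mc_settings <- function(n_photons = 2e5, seed = 1L, g = 0.9, n_tissue = 1.37,
                        w_min = 1e-4, p_roulette = 0.1, max_path_cm = 50) {
  if (g < 0 || g >= 1) stop("g must lie in [0, 1)", call. = FALSE)
  if (n_photons < 1) stop("n_photons must be positive", call. = FALSE)
  structure(list(n_photons = as.integer(n_photons), seed = as.integer(seed),
                 g = g, n_tissue = n_tissue, w_min = w_min,
                 p_roulette = p_roulette, max_path_cm = max_path_cm),
            class = "mc_settings")
}

cos_acceptance <- function(geometry, settings) {
  s <- geometry$na / settings$n_tissue
  if (s >= 1) 0 else sqrt(1 - s^2)
}

#' Photon Monte Carlo for the contact probe on a semi-infinite medium
#'
#' Launches photons from the source fiber face (collimated, uniform over the
#' core), propagates them with Henyey-Greenstein scattering and implicit
#' capture, applies Fresnel reflection/refraction at the tissue-probe
#' interface, and detects photons exiting within the acceptance cone at each
#' detector separation (exact azimuthal arc-fraction weighting over the
#' detector disks).  Returns per-separation reflectance (detected fraction
#' of launched power), Monte Carlo standard errors, the exit-path records
#' needed for white-Monte-Carlo rescaling, and an exact energy ledger.
#'
#' @param mua Absorption coefficient, cm^-1 (>= 0).
#' @param musp Reduced scattering coefficient, cm^-1 (> 0).
#' @param geometry A [probe_geometry()].
#' @param settings An [mc_settings()].
#' @param record_paths Keep per-photon exit records (needed for rescaling)?
#' @param full_acceptance Disable the numerical-aperture cone (useful for
#'   total-reflectance checks).
#' @param index_matched Treat the boundary as refractive-index matched.
#' @return List with `reflectance`, `se`, `records` (data.frame `L`, `r`,
#'   `w`), and `ledger`.
#' @export
run_photon_mc <- function(mua, musp, geometry, settings,
                          record_paths = FALSE, full_acceptance = FALSE,
                          index_matched = FALSE) {
  stopifnot(inherits(geometry, "probe_geometry"),
            inherits(settings, "mc_settings"))
  if (musp <= 0) stop("musp must be positive", call. = FALSE)
  if (mua < 0) stop("mua must be nonnegative", call. = FALSE)
  mus <- musp / (1 - settings$g)
  n_ext <- if (index_matched) settings$n_tissue else geometry$n_fiber
  ca <- if (full_acceptance) 0 else cos_acceptance(geometry, settings)
  rmax <- max(geometry$separations_cm) + geometry$fiber_radius_cm
  out <- mc_transport_cpp(mua, mus, settings$g, settings$n_tissue, n_ext,
                          geometry$fiber_radius_cm, geometry$separations_cm,
                          geometry$fiber_radius_cm, ca,
                          settings$n_photons, settings$w_min,
                          settings$p_roulette, settings$max_path_cm,
                          record_paths, rmax, as.double(settings$seed))
  n <- out$n_photons
  refl <- out$det_w / n
  varc <- pmax(out$det_w2 / n - refl^2, 0)
  ledger <- c(specular = out$specular / n, diffuse = out$diffuse / n,
              absorbed = out$absorbed / n, terminated = out$terminated / n)
  records <- NULL
  if (record_paths) {
    records <- as.data.frame(out$records)
    attr(records, "n_photons") <- n
    attr(records, "geometry") <- geometry
    attr(records, "cos_accept") <- ca
    attr(records, "mua") <- mua
  }
  list(reflectance = refl, se = sqrt(varc / n), records = records,
       ledger = ledger)
}

#' White-Monte-Carlo rescaling of zero-absorption path records
#'
#' Reweights each detected photon of a `mua = 0` run by `exp(-mua * L)` and
#' re-accumulates per-separation reflectance, which is exact in expectation
#' for homogeneous absorption.  One scattering-only simulation therefore
#' yields reflectance at any absorption level.
#'
#' @param records Exit-path records from [run_photon_mc()] run at `mua = 0`
#'   with `record_paths = TRUE`, or the prepared detection structure from
#'   [prepare_rescale()].
#' @param mua Absorption coefficient(s), cm^-1 (each >= 0).
#' @param geometry Probe geometry (defaults to the one stored in `records`).
#' @return If one `mua`: list with `reflectance` and `se` per separation.
#'   If several: matrix `length(mua) x n_separations` of reflectance.
#' @export
rescale_white_mc <- function(records, mua, geometry = NULL) {
  prep <- if (inherits(records, "drsfit_rescale")) records else
    prepare_rescale(records, geometry)
  if (any(mua < 0)) stop("mua must be nonnegative", call. = FALSE)
  n <- prep$n_photons
  nd <- length(prep$per_det)
  if (length(mua) == 1L) {
    refl <- se <- numeric(nd)
    for (k in seq_len(nd)) {
      pd <- prep$per_det[[k]]
      c_i <- pd$fw * exp(-mua * pd$L)
      s1 <- sum(c_i); s2 <- sum(c_i^2)
      refl[k] <- s1 / n
      se[k] <- sqrt(pmax(s2 / n - (s1 / n)^2, 0) / n)
    }
    list(reflectance = refl, se = se)
  } else {
    out <- matrix(0, length(mua), nd)
    for (k in seq_len(nd)) {
      pd <- prep$per_det[[k]]
      # outer product over absorption levels; records are few enough
      out[, k] <- as.numeric(exp(-outer(mua, pd$L)) %*% pd$fw) / n
    }
    out
  }
}

#' @rdname rescale_white_mc
#' @export
prepare_rescale <- function(records, geometry = NULL) {
  if (is.null(geometry)) geometry <- attr(records, "geometry")
  if (is.null(geometry)) stop("geometry required", call. = FALSE)
  if (!isTRUE(all.equal(attr(records, "mua"), 0))) {
    stop("white-MC rescaling requires records generated at mua = 0",
         call. = FALSE)
  }
  n <- attr(records, "n_photons")
  per_det <- lapply(geometry$separations_cm, function(d) {
    f <- arc_fraction_cpp(records$r, d, geometry$fiber_radius_cm)
    sel <- which(f > 0)
    list(L = records$L[sel], fw = f[sel] * records$w[sel])
  })
  structure(list(per_det = per_det, n_photons = n, geometry = geometry),
            class = "drsfit_rescale")
}
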