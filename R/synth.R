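#' Cohort specification for synthetic paired pre-/post-MB measurements
#'
#' Defines the distributions from which subject ground truths are drawn.
#' Ranges are anchored to the observed clinical cohort: pre-MB absorption
#' at 665 nm between 0.03 and 0.36 cm^-1, reduced scattering amplitude
#' between 4.8 and 13.2 cm^-1, oxygen saturation between ~5% and 100%, and
#' total MB uptake between 0 and 311 uM with a point mass at zero
#' (some subjects retain no measurable MB after flushing).
#'
#' The pre-to-post effect rules emulate the observed trends: MB total drawn
#' log-uniformly; the dimer fraction of monomer units rising with total MB
#' (`fd = 0.7 * MB / (MB + 30)`); an SO2 reduction increasing with MB; and
#' a multiplicative decrease in scattering amplitude.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param mua665_pre Log-uniform range of pre-MB hemoglobin-driven
#'   absorption at 665 nm, cm^-1.
#' @param musp665_pre Uniform range of the pre-MB scattering amplitude,
#'   cm^-1.
#' @param b_range Uniform range of the scattering power.
#' @param so2_pre Uniform range of pre-MB SO2 (fraction).
#' @param mb_range Log-uniform range of nonzero post-MB total MB, uM.
#' @param mb_zero_prob Probability of zero MB uptake.
#' @param so2_drop_scale Maximum mean SO2 reduction (% points) at high MB.
#' @param musp_post_factor Uniform range of the post/pre scattering
#'   amplitude ratio.
#' @param contact_fail_prob Per-fiber probability of a contact failure.
#' @param snr Target median signal-to-noise ratio of simulated raw spectra
#'   (`Inf` for noise-free).
#' @param seed Master seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 13L,
                        mua665_pre = c(0.03, 0.36),
                        musp665_pre = c(4.8, 13.2),
                        b_range = c(0.7, 1.6),
                        so2_pre = c(0.056, 1),
                        mb_range = c(0.1, 311),
                        mb_zero_prob = 2 / 13,
                        so2_drop_scale = 55,
                        musp_post_factor = c(0.45, 0.95),
                        contact_fail_prob = 0.1,
                        snr = 100, seed = 1L) {
  if (n_subjects < 2L) stop("need at least 2 subjects", call. = FALSE)
  rngs <- list(mua665_pre = mua665_pre, musp665_pre = musp665_pre,
               b_range = b_range, so2_pre = so2_pre, mb_range = mb_range,
               musp_post_factor = musp_post_factor)
  for (nm in names(rngs)) {
    r <- rngs[[nm]]
    if (length(r) != 2L || diff(r) <= 0 || any(r < 0)) {
      stop("range ", nm, " must be positive-length and nonnegative",
           call. = FALSE)
    }
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 mua665_pre = mua665_pre, musp665_pre = musp665_pre,
                 b_range = b_range, so2_pre = so2_pre, mb_range = mb_range,
                 mb_zero_prob = mb_zero_prob,
                 so2_drop_scale = so2_drop_scale,
                 musp_post_factor = musp_post_factor,
                 contact_fail_prob = contact_fail_prob,
                 snr = snr, seed = as.integer(seed)),
            class = "cohort_spec")
}

# per-draw seed derived from a master seed, kept inside the valid integer
# range whatever the master seed is
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000 + i) %% (.Machine$integer.max - 100))
}

#' Monomer/dimer partition of a total methylene blue concentration
#'
#' `mb_dimer_fraction()` models the equilibrium dimer fraction of monomer
#' units as rising with total concentration, `0.7 * MB / (MB + 30)`.
#' `split_mb()` converts a total MB concentration (in monomer-unit uM)
#' into the monomer and dimer amplitudes of the chromophore basis (a
#' dimer binds two monomer units, so `MBmono + 2 * MBdimer` equals the
#' total).
#'
#' @param mb Total MB concentration, monomer-unit uM.
#' @param dimer_fraction Fraction of monomer units bound in dimers.
#' @return `split_mb`: named vector `c(MBmono, MBdimer)` of basis
#'   amplitudes, uM. `mb_dimer_fraction`: the fraction.
#' @export
split_mb <- function(mb, dimer_fraction = mb_dimer_fraction(mb)) {
  c(MBmono = mb * (1 - dimer_fraction), MBdimer = mb * dimer_fraction / 2)
}

#' @rdname split_mb
#' @export
mb_dimer_fraction <- function(mb) 0.7 * mb / (mb + 30)

#' Hemoglobin concentrations matching a target absorption and saturation
#'
#' Solves for the oxy/deoxy-hemoglobin concentrations whose composed
#' absorption at 665 nm equals `mua665` at oxygen saturation `so2_frac`.
#'
#' @param mua665 Target hemoglobin absorption at 665 nm, cm^-1.
#' @param so2_frac Oxygen saturation as a fraction in \[0, 1\].
#' @param basis A [chromophore_basis()].
#' @return Named vector `c(HbO2, Hb)`, uM.
#' @export
hb_for_mua665 <- function(mua665, so2_frac, basis) {
  e <- basis_eps665(basis)
  thb <- mua665 / (so2_frac * e[["HbO2"]] + (1 - so2_frac) * e[["Hb"]])
  c(HbO2 = so2_frac * thb, Hb = (1 - so2_frac) * thb)
}

#' Parameter-sweep ground truths for validation experiments
#'
#' Draws independent single-placement truths for recovery sweeps: total MB
#' uniform over `mb_range` (partitioned by [split_mb()]), scattering
#' amplitude uniform over `a_range`, power uniform over `b_range`, and the
#' hemoglobin background log-uniform in absorption over `mua665_hb` at a
#' uniform saturation.  The `pre` slot carries the hemoglobin-only truth,
#' the `post` slot adds the MB terms.
#'
#' @param n Number of draws.
#' @param basis A [chromophore_basis()].
#' @param seed Master seed; draw i simulates with seed `seed * 1000 + i`.
#' @param mb_range Uniform range of total MB, uM.
#' @param a_range Uniform range of mu_s'(665), cm^-1.
#' @param b_range Uniform range of the scattering power.
#' @param so2_range Uniform range of SO2 (fraction).
#' @param mua665_hb Log-uniform range of hemoglobin absorption at 665 nm,
#'   cm^-1.
#' @param snr Target median SNR carried by each truth.
#' @return List of `subject_truth` objects (see [sample_cohort()]).
#' @export
sweep_truths <- function(n, basis, seed = 1L, mb_range = c(0, 15),
                         a_range = c(4, 14), b_range = c(0.7, 1.6),
                         so2_range = c(0.056, 1),
                         mua665_hb = c(0.03, 0.36), snr = 100) {
  old_rng <- save_rng()
  on.exit(restore_rng(old_rng), add = TRUE)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    a <- stats::runif(1, a_range[1], a_range[2])
    b <- stats::runif(1, b_range[1], b_range[2])
    so2 <- stats::runif(1, so2_range[1], so2_range[2])
    mua_hb <- exp(stats::runif(1, log(mua665_hb[1]), log(mua665_hb[2])))
    mb <- stats::runif(1, mb_range[1], mb_range[2])
    hb <- hb_for_mua665(mua_hb, so2, basis)
    structure(list(
      subject = sprintf("V%02d", i),
      pre = list(conc = c(hb, MBmono = 0, MBdimer = 0)[chromophore_names],
                 a = a, b = b),
      post = list(conc = c(hb, split_mb(mb))[chromophore_names],
                  a = a, b = b),
      bad_fibers = integer(0), snr = snr,
      seed = derive_seed(seed, i)), class = "subject_truth")
  })
}

#' Draw a cohort of subject ground truths
#'
#' Deterministic under the spec's master seed.  Each subject carries pre-
#' and post-MB concentration vectors and scattering parameters, per-fiber
#' contact-failure flags, and the target SNR.  Post-MB absorption spectra
#' are kept inside the lookup-table validity range by capping extreme MB
#' draws at the largest concentration whose absorption stays below
#' `mua_cap` across 450-750 nm.
#'
#' @param spec A [cohort_spec()].
#' @param basis A [chromophore_basis()] (converts target optical
#'   properties into concentrations).
#' @param n_fibers Number of detector fibers.
#' @param mua_cap Absorption ceiling for generated spectra, cm^-1.
#' @return List of subject truths (class `subject_truth` each).
#' @export
sample_cohort <- function(spec, basis, n_fibers = 8L, mua_cap = 75) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_rng <- save_rng()
  on.exit(restore_rng(old_rng), add = TRUE)
  set.seed(spec$seed)
  lapply(seq_len(spec$n_subjects), function(i) {
    mua_pre <- exp(stats::runif(1, log(spec$mua665_pre[1]),
                                log(spec$mua665_pre[2])))
    so2p <- stats::runif(1, spec$so2_pre[1], spec$so2_pre[2])
    hb_pre <- hb_for_mua665(mua_pre, so2p, basis)
    a_pre <- stats::runif(1, spec$musp665_pre[1], spec$musp665_pre[2])
    b_pre <- stats::runif(1, spec$b_range[1], spec$b_range[2])

    mb <- if (stats::runif(1) < spec$mb_zero_prob) 0 else
      exp(stats::runif(1, log(spec$mb_range[1]), log(spec$mb_range[2])))
    # SO2 reduction grows with MB uptake
    drop_pct <- spec$so2_drop_scale * mb / (mb + 50) +
      stats::rnorm(1, 0, 8) * (mb > 0)
    so2_post <- min(max(100 * so2p - drop_pct, 0.0001), 100) / 100
    thb_fac <- stats::runif(1, 0.8, 1.25)
    hb_post <- hb_for_mua665(mua_pre * thb_fac, so2_post, basis)
    a_post <- a_pre * stats::runif(1, spec$musp_post_factor[1],
                                   spec$musp_post_factor[2])
    b_post <- b_pre + stats::rnorm(1, 0, 0.1)

    conc_pre <- c(hb_pre, MBmono = 0, MBdimer = 0)[chromophore_names]
    mbamp <- split_mb(mb)
    conc_post <- c(hb_post, mbamp)[chromophore_names]
    # cap MB so the post-MB absorption spectrum stays inside the LUT hull
    mua_post <- compose_mua(conc_post, basis)
    if (max(mua_post) > mua_cap) {
      scale <- {
        mua_hb <- compose_mua(c(hb_post, MBmono = 0,
                                MBdimer = 0)[chromophore_names], basis)
        mua_mb <- mua_post - mua_hb
        i_max <- which.max(mua_post)
        max((mua_cap - mua_hb[i_max]) / mua_mb[i_max], 0)
      }
      conc_post[c("MBmono", "MBdimer")] <-
        conc_post[c("MBmono", "MBdimer")] * scale
    }
    bad <- which(stats::runif(n_fibers) < spec$contact_fail_prob)
    structure(list(
      subject = sprintf("S%02d", i),
      pre = list(conc = conc_pre, a = a_pre, b = b_pre),
      post = list(conc = conc_post, a = a_post, b = b_post),
      bad_fibers = bad, snr = spec$snr,
      seed = derive_seed(spec$seed, i)), class = "subject_truth")
  })
}

#' Smooth synthetic system spectral response
#'
#' Lamp-times-spectrometer efficiency model: a broad positive curve in
#' counts per ms per unit reflectance.  Its exact shape cancels in the
#' calibration ratio; it is deliberately non-flat so the correction chain
#' is genuinely exercised.
#'
#' @param wavelength Wavelengths, nm.
#' @return Response values (counts / ms per unit reflectance).
#' @export
system_response <- function(wavelength) {
  5e6 * exp(-0.5 * ((wavelength - 620) / 160)^2) *
    (1 + 0.25 * sin(wavelength / 40))
}

#' Simulate one raw measurement set from known ground truth
#'
#' Inverts the correction chain: true per-fiber reflectance from the
#' forward model is multiplied by the synthetic system response and an
#' integration time chosen by the adaptive half-dynamic-range rule, dark
#' offsets are added, and shot-shaped noise (scaled to the target median
#' SNR, plus Gaussian read noise) is injected.  Fibers flagged as contact
#' failures are replaced by specular-contaminated or noise-floor spectra.
#' Dark and integrating-sphere calibration spectra are emitted alongside,
#' so [calibrate_measurement()] applies exactly as for real data.
#'
#' @param truth A subject truth from [sample_cohort()], or a list with
#'   elements `conc`, `a`, `b` (then `condition` decides the tag only).
#' @param condition `"pre"` or `"post"`.
#' @param lut,basis Forward model components.
#' @param geometry Probe geometry (defaults to the LUT's).
#' @param snr Target median SNR (`Inf` = noise-free); defaults to the
#'   truth's.
#' @param seed RNG seed; defaults to the truth's.
#' @param dynamic_range,read_noise,dark_rate Instrument model parameters.
#' @return A [measurement_set()].
#' @export
simulate_measurement <- function(truth, condition = c("pre", "post"),
                                 lut, basis, geometry = lut$geometry,
                                 snr = NULL, seed = NULL,
                                 dynamic_range = 65535, read_noise = 6,
                                 dark_rate = 0.2) {
  condition <- match.arg(condition)
  st <- if (inherits(truth, "subject_truth")) truth[[condition]] else truth
  if (is.null(snr)) snr <- if (!is.null(truth$snr)) truth$snr else Inf
  if (is.null(seed)) seed <- if (!is.null(truth$seed)) truth$seed else 1L
  seed <- seed + 17L * (condition == "post")
  bad <- if (inherits(truth, "subject_truth")) truth$bad_fibers else integer(0)
  subject <- if (!is.null(truth$subject)) truth$subject else NA_character_

  wl <- as.numeric(basis$wavelength)
  nf <- length(geometry$separations_cm)
  R_true <- forward_spectra(st$conc, st$a, st$b, lut, basis,
                            wavelengths = wl, fibers = seq_len(nf))
  resp <- system_response(wl)
  old_rng <- save_rng()
  on.exit(restore_rng(old_rng), add = TRUE)
  set.seed(as.integer(as.numeric(seed) %% (.Machine$integer.max - 100)))

  # the shot-noise scale is set from the reference (healthy) signal, so a
  # contact-failed fiber keeps the instrument's noise floor while its
  # signal collapses -- its SNR drops instead of being renormalized
  noisy <- function(counts_nl, target_snr, ref_nl = counts_nl) {
    counts_nl <- pmax(counts_nl, 0)
    if (!is.finite(target_snr)) return(counts_nl)
    ref_nl <- pmax(ref_nl, 0)
    sig <- ref_nl - min(ref_nl)
    band <- wl >= 500 & wl <= 750
    nat <- stats::median(sig[band] / sqrt(pmax(ref_nl[band], 1)))
    kappa <- max(nat / target_snr, 0)
    sigma <- sqrt(kappa^2 * counts_nl + read_noise^2)
    pmax(counts_nl + stats::rnorm(length(counts_nl), 0, sigma), 0)
  }

  t_cal <- 100
  fibs <- vector("list", nf)
  for (k in seq_len(nf)) {
    Rk_good <- R_true[, k]
    Rk <- Rk_good
    if (k %in% bad) {
      # alternate failure modes: specular contamination / loss of optical
      # coupling (essentially no collected light)
      Rk <- if (k %% 2 == 0) rep(2.5, length(wl)) else Rk * 1e-4
    }
    dark_nl <- dark_rate * 50
    init_counts <- noisy(Rk * resp * 50 + dark_nl, snr,
                         ref_nl = Rk_good * resp * 50 + dark_nl)
    t_k <- tryCatch(
      select_integration_time(
        raw_spectrum(wl, init_counts, 50, fiber = k),
        dark_nl, dynamic_range = dynamic_range),
      error = function(e) 10)
    dk_nl <- dark_rate * t_k
    raw_counts <- noisy(Rk * resp * t_k + dk_nl, snr,
                        ref_nl = Rk_good * resp * t_k + dk_nl)
    dark_counts <- noisy(rep(dk_nl, length(wl)), snr * 10)
    cal_nl <- resp * t_cal + dark_rate * t_cal
    cal_counts <- noisy(cal_nl, snr * 10)
    cald_counts <- noisy(rep(dark_rate * t_cal, length(wl)), snr * 10)
    fibs[[k]] <- list(
      raw = raw_spectrum(wl, raw_counts, t_k, fiber = k, kind = "sample",
                         condition = condition),
      dark = raw_spectrum(wl, dark_counts, t_k, fiber = k, kind = "dark"),
      cal = raw_spectrum(wl, cal_counts, t_cal, fiber = k,
                         kind = "calibration"),
      cal_dark = raw_spectrum(wl, cald_counts, t_cal, fiber = k,
                              kind = "calibration_dark"))
  }
  measurement_set(fibs, subject = subject, condition = condition)
}

#' Parameter-recovery experiment over a synthetic cohort
#'
#' Simulates each subject/condition at each noise level, runs the full
#' calibration + QC + inversion pipeline, and tabulates truth against
#' estimate.  Non-convergent or QC-rejected measurements are excluded and
#' counted.
#'
#' @param truths Subject truths from [sample_cohort()].
#' @param lut,basis,geometry Forward model components.
#' @param snr_levels Target SNR levels to sweep.
#' @param conditions Conditions to include.
#' @param config_fn Function `(condition) -> fit_config`; the default fits
#'   pre-MB data with the hemoglobin-only model.
#' @return `data.frame` with one row per fit: truth and estimates of
#'   mua665, musp665, SO2 and total MB, plus `srse` and exclusion flags.
#'   A summary (bias/RMSE per quantity per SNR) is attached as attribute
#'   `"summary"`.
#' @export
recovery_experiment <- function(truths, lut, basis, geometry = lut$geometry,
                                snr_levels = 100,
                                conditions = c("pre", "post"),
                                config_fn = NULL) {
  if (is.null(config_fn)) {
    config_fn <- function(condition) fit_config(mode = condition)
  }
  rows <- list()
  for (snr in snr_levels) {
    for (tr in truths) {
      for (cond in conditions) {
        st <- tr[[cond]]
        true_mua665 <- drop(basis_eps665(basis) %*% st$conc)
        true_mb <- compute_total_mb(st$conc)
        true_so2 <- 100 * st$conc[["HbO2"]] /
          sum(st$conc[c("HbO2", "Hb")])
        mset <- simulate_measurement(tr, cond, lut, basis, geometry,
                                     snr = snr)
        fit <- tryCatch(
          drs_fit(mset, lut, basis, config = config_fn(cond)),
          drsfit_insufficient_fibers = function(e) NULL,
          error = function(e) NULL)
        excluded <- is.null(fit) || fit$convergence$flagged
        rows[[length(rows) + 1L]] <- data.frame(
          subject = tr$subject, condition = cond, snr = snr,
          true_mua665 = true_mua665, true_musp665 = st$a,
          true_so2 = true_so2, true_mb = true_mb,
          est_mua665 = if (excluded) NA_real_ else fit$mua665,
          est_musp665 = if (excluded) NA_real_ else fit$musp665,
          est_so2 = if (excluded) NA_real_ else fit$so2,
          est_mb = if (excluded) NA_real_ else fit$mb_total,
          srse = if (excluded) NA_real_ else fit$srse,
          excluded = excluded)
      }
    }
  }
  out <- do.call(rbind, rows)
  qty <- c("mua665", "musp665", "so2", "mb")
  summ <- do.call(rbind, lapply(split(out, out$snr), function(d) {
    do.call(rbind, lapply(qty, function(q) {
      err <- d[[paste0("est_", q)]] - d[[paste0("true_", q)]]
      data.frame(snr = d$snr[1], quantity = q,
                 bias = mean(err, na.rm = TRUE),
                 rmse = sqrt(mean(err^2, na.rm = TRUE)),
                 n = sum(is.finite(err)),
                 n_excluded = sum(d$excluded))
    }))
  }))
  rownames(summ) <- NULL
  attr(out, "summary") <- summ
  out
}

#' Simulate raw measurement sets from a fitted model
#'
#' Uses the fitted concentrations and scattering parameters as ground truth
#' and regenerates noisy synthetic raw measurements through the instrument
#' model.
#'
#' @param object A [drs_fit()] result.
#' @param nsim Number of measurement sets.
#' @param seed RNG seed.
#' @param snr Target median SNR.
#' @param ... Unused.
#' @return List of [measurement_set()] objects.
#' @export
simulate.drs_fit <- function(object, nsim = 1, seed = 1L, snr = 100, ...) {
  cf <- object$coefficients
  truth <- list(conc = cf[chromophore_names], a = cf[["a"]], b = cf[["b"]])
  lapply(seq_len(nsim), function(i) {
    simulate_measurement(truth, condition = object$condition,
                         lut = object$lut, basis = object$basis,
                         snr = snr, seed = seed + i - 1L)
  })
}
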