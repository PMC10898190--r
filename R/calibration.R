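#' Raw spectrometer spectrum
#'
#' One acquisition from one detector fiber: counts versus wavelength with
#' its integration time, fiber index and condition tag.
#'
#' @param wavelength Wavelengths, nm.
#' @param counts Detector counts (>= 0).
#' @param integration_time_ms Integration time, ms (> 0).
#' @param fiber Detector fiber index (1-8).
#' @param kind One of `"sample"`, `"dark"`, `"calibration"`,
#'   `"calibration_dark"`.
#' @param condition Condition tag, e.g. `"pre"` or `"post"`.
#' @return Object of class `raw_spectrum`.
#' @export
raw_spectrum <- function(wavelength, counts, integration_time_ms, fiber = 1L,
                         kind = c("sample", "dark", "calibration",
                                  "calibration_dark"),
                         condition = NA_character_) {
  kind <- match.arg(kind)
  if (length(wavelength) != length(counts)) {
    stop("wavelength and counts lengths differ", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (integration_time_ms <= 0) {
    stop("integration time must be positive", call. = FALSE)
  }
  structure(list(wavelength = as.numeric(wavelength),
                 counts = as.numeric(counts),
                 integration_time_ms = integration_time_ms,
                 fiber = as.integer(fiber), kind = kind,
                 condition = condition),
            class = "raw_spectrum")
}

check_same_grid <- function(a, b) {
  if (length(a$wavelength) != length(b$wavelength) ||
      any(abs(a$wavelength - b$wavelength) > 1e-9)) {
    stop(errorCondition("wavelength grids do not match",
                        class = "drsfit_grid_mismatch"))
  }
}

# shot + read noise model on counts, in count units
counts_noise <- function(counts, read_noise) {
  sqrt(pmax(counts, 0) + read_noise^2)
}

#' Calibrate a raw spectrum
#'
#' Applies the standard correction chain: dark subtraction, integration-time
#' normalization, and division by the (dark-subtracted, time-normalized)
#' integrating-sphere calibration spectrum:
#' `R = [(raw - dark) / t_raw] / [(cal - cal_dark) / t_cal]`.
#'
#' Wavelengths where the calibration numerator does not exceed `mask_k`
#' times its noise estimate are masked (`NA` with the mask recorded), since
#' the ratio is undefined there.  A per-wavelength noise estimate for the
#' calibrated reflectance is propagated from a shot + read-noise model.
#'
#' @param raw,dark,cal,cal_dark [raw_spectrum()] objects on one grid.
#' @param read_noise Read-noise floor, counts RMS.
#' @param mask_k Mask threshold in units of calibration noise.
#' @return Object of class `calibrated_spectrum`: list with `wavelength`,
#'   `reflectance`, `noise`, `mask`, `fiber`.
#' @export
correct_spectrum <- function(raw, dark, cal, cal_dark, read_noise = 6,
                             mask_k = 3) {
  for (s in list(dark, cal, cal_dark)) check_same_grid(raw, s)
  check_same_grid(raw, dark)
  num <- (raw$counts - dark$counts) / raw$integration_time_ms
  den <- (cal$counts - cal_dark$counts) / cal$integration_time_ms
  den_noise <- sqrt(counts_noise(cal$counts, read_noise)^2 +
                    counts_noise(cal_dark$counts, read_noise)^2) /
    cal$integration_time_ms
  masked <- den <= mask_k * den_noise
  if (all(masked)) {
    stop(errorCondition("calibration spectrum below noise floor everywhere",
                        class = "drsfit_unusable_fiber"))
  }
  refl <- num / den
  refl[masked] <- NA_real_
  num_noise <- sqrt(counts_noise(raw$counts, read_noise)^2 +
                    counts_noise(dark$counts, read_noise)^2) /
    raw$integration_time_ms
  noise <- abs(refl) * sqrt((num_noise / pmax(abs(num), 1e-12))^2 +
                            (den_noise / pmax(abs(den), 1e-12))^2)
  # where the signal is near zero the ratio error is calibration-limited
  noise <- pmax(noise, num_noise / pmax(abs(den), 1e-12))
  noise[masked] <- NA_real_
  structure(list(wavelength = raw$wavelength, reflectance = refl,
                 noise = noise, mask = masked, fiber = raw$fiber),
            class = "calibrated_spectrum")
}

#' Adaptive integration time from an initial probe measurement
#'
#' Given an initial acquisition, assumes detected signal scales linearly
#' with integration time and returns the time that would put the spectral
#' peak at half the spectrometer dynamic range:
#' `t_new = t * (0.5 * dynamic_range) / max(raw - dark)`, clipped to
#' `bounds`.  A saturated input (peak at or above the dynamic range) raises
#' an error of class `drsfit_saturated`, signalling re-measurement at a
#' shorter time.
#'
#' @param raw Initial [raw_spectrum()].
#' @param dark Matching dark spectrum (or a scalar dark level).
#' @param dynamic_range Full-scale counts of the spectrometer.
#' @param bounds Allowed integration-time range, ms.
#' @return Integration time in ms.
#' @export
select_integration_time <- function(raw, dark, dynamic_range = 65535,
                                    bounds = c(10, 5000)) {
  dk <- if (inherits(dark, "raw_spectrum")) dark$counts else dark
  if (max(raw$counts) >= dynamic_range) {
    stop(errorCondition("input saturated: re-measure at reduced time",
                        class = "drsfit_saturated"))
  }
  peak <- max(raw$counts - dk)
  if (peak <= 0) stop("no signal above dark level", call. = FALSE)
  t_new <- raw$integration_time_ms * (0.5 * dynamic_range) / peak
  min(max(t_new, bounds[1]), bounds[2])
}

#' Measurement set for one probe placement
#'
#' Bundles, per detector fiber, the sample/dark/calibration/calibration-dark
#' raw spectra for one probe placement, with subject id and condition tag.
#'
#' @param fibers List (one element per fiber) of lists with components
#'   `raw`, `dark`, `cal`, `cal_dark`, each a [raw_spectrum()].
#' @param subject Subject identifier.
#' @param condition `"pre"` or `"post"` (MB administration).
#' @return Object of class `measurement_set`.
#' @export
measurement_set <- function(fibers, subject = NA_character_,
                            condition = c("pre", "post")) {
  condition <- match.arg(condition)
  for (f in fibers) {
    if (!all(c("raw", "dark", "cal", "cal_dark") %in% names(f))) {
      stop("each fiber needs raw, dark, cal and cal_dark spectra",
           call. = FALSE)
    }
    check_same_grid(f$raw, f$dark)
    check_same_grid(f$raw, f$cal)
    check_same_grid(f$raw, f$cal_dark)
  }
  structure(list(fibers = fibers, subject = subject, condition = condition),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("Measurement set: subject %s, %s-MB, %d fibers\n",
              x$subject, x$condition, length(x$fibers)))
  invisible(x)
}

#' Calibrate every fiber of a measurement set
#'
#' @param set A [measurement_set()].
#' @inheritParams correct_spectrum
#' @return Object of class `calibrated_set`: list of
#'   [correct_spectrum()] results plus the set metadata.
#' @export
calibrate_measurement <- function(set, read_noise = 6, mask_k = 3) {
  stopifnot(inherits(set, "measurement_set"))
  spectra <- lapply(set$fibers, function(f) {
    tryCatch(correct_spectrum(f$raw, f$dark, f$cal, f$cal_dark,
                              read_noise = read_noise, mask_k = mask_k),
             drsfit_unusable_fiber = function(e) NULL)
  })
  structure(list(spectra = spectra, subject = set$subject,
                 condition = set$condition),
            class = "calibrated_set")
}

#' Detector-fiber quality control
#'
#' Flags fibers unusable for inversion: insufficient signal-to-noise over
#' the fit band (median signal/noise below `snr_min`), or apparent loss of
#' surface contact (specular contamination pushing the corrected spectrum
#' above a physical reflectance ceiling over more than `ceiling_frac` of
#' the band).  At least four usable fibers are required for a reliable
#' inversion; fewer raises an error of class `drsfit_insufficient_fibers`.
#'
#' @param cal_set A [calibrate_measurement()] result.
#' @param snr_min Minimum median SNR over the QC band.
#' @param ceiling Physical reflectance ceiling.
#' @param ceiling_frac Band fraction above the ceiling that flags a fiber.
#' @param band QC wavelength band, nm.
#' @param min_fibers Minimum number of usable fibers.
#' @return Integer vector of usable fiber indices.
#' @export
detector_qc <- function(cal_set, snr_min = 10, ceiling = 1.0,
                        ceiling_frac = 0.05, band = c(500, 750),
                        min_fibers = 4L) {
  stopifnot(inherits(cal_set, "calibrated_set"))
  usable <- integer(0)
  for (i in seq_along(cal_set$spectra)) {
    cs <- cal_set$spectra[[i]]
    if (is.null(cs)) next
    sel <- cs$wavelength >= band[1] & cs$wavelength <= band[2] & !cs$mask
    if (!any(sel)) next
    snr <- stats::median(cs$reflectance[sel] / cs$noise[sel], na.rm = TRUE)
    above <- mean(cs$reflectance[sel] > ceiling, na.rm = TRUE)
    if (is.finite(snr) && snr >= snr_min && above <= ceiling_frac) {
      usable <- c(usable, i)
    }
  }
  if (length(usable) < min_fibers) {
    stop(errorCondition(
      sprintf("only %d usable detector fibers (need >= %d): unfit for inversion",
              length(usable), min_fibers),
      class = "drsfit_insufficient_fibers"))
  }
  usable
}

#' Write or read a measurement set as columnar text plus a manifest
#'
#' Each (fiber, kind) spectrum is one CSV (`wavelength_nm, counts`); a JSON
#' manifest binds the files with integration times, fiber indices, subject
#' and condition.
#'
#' @param set A [measurement_set()].
#' @param dir Output directory (created if needed).
#' @param manifest Path to a manifest JSON written by
#'   [write_measurement_set()].
#' @return `write_measurement_set` returns the manifest path;
#'   `read_measurement_set` the restored [measurement_set()].
#' @export
write_measurement_set <- function(set, dir) {
  stopifnot(inherits(set, "measurement_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (i in seq_along(set$fibers)) {
    for (kind in c("raw", "dark", "cal", "cal_dark")) {
      sp <- set$fibers[[i]][[kind]]
      fn <- sprintf("fiber%02d_%s.csv", i, kind)
      utils::write.csv(data.frame(wavelength_nm = sp$wavelength,
                                  counts = sp$counts),
                       file.path(dir, fn), row.names = FALSE)
      entries[[length(entries) + 1L]] <- list(
        fiber = i, kind = kind, file = fn,
        integration_time_ms = sp$integration_time_ms)
    }
  }
  manifest <- list(subject = set$subject, condition = set$condition,
                   spectra = entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  path
}

#' @rdname write_measurement_set
#' @export
read_measurement_set <- function(manifest) {
  m <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  dir <- dirname(manifest)
  fibs <- list()
  for (e in m$spectra) {
    d <- utils::read.csv(file.path(dir, e$file))
    kind_tag <- switch(e$kind, raw = "sample", dark = "dark",
                       cal = "calibration", cal_dark = "calibration_dark")
    sp <- raw_spectrum(d$wavelength_nm, d$counts, e$integration_time_ms,
                       fiber = e$fiber, kind = kind_tag,
                       condition = m$condition)
    i <- as.character(e$fiber)
    if (is.null(fibs[[i]])) fibs[[i]] <- list()
    fibs[[i]][[e$kind]] <- sp
  }
  fibs <- fibs[order(as.integer(names(fibs)))]
  measurement_set(unname(fibs), subject = m$subject, condition = m$condition)
}
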