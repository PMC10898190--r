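wl <- seq(450, 750, by = 1)
resp <- system_response(wl)

mk <- function(counts, t, fiber = 1L, kind = "sample") {
  raw_spectrum(wl, counts, t, fiber = fiber, kind = kind)
}

test_that("the correction chain inverts a noise-free instrument model", {
  R_true <- 0.2 + 0.1 * sin(wl / 30)
  dark_s <- rep(12, length(wl)); dark_c <- rep(7, length(wl))
  raw <- mk(R_true * resp * 40 + dark_s, 40)
  dark <- mk(dark_s, 40, kind = "dark")
  cal <- mk(resp * 100 + dark_c, 100, kind = "calibration")
  cald <- mk(dark_c, 100, kind = "calibration_dark")
  cs <- correct_spectrum(raw, dark, cal, cald)
  expect_equal(cs$reflectance, R_true, tolerance = 1e-12)
  expect_true(all(!cs$mask))
  expect_true(all(cs$noise > 0))
})

test_that("calibration removes any overall system gain", {
  R_true <- rep(0.15, length(wl))
  build <- function(gain) {
    raw <- mk(R_true * gain * resp * 50, 50)
    dark <- mk(rep(0, length(wl)), 50, kind = "dark")
    cal <- mk(gain * resp * 100, 100, kind = "calibration")
    cald <- mk(rep(0, length(wl)), 100, kind = "calibration_dark")
    correct_spectrum(raw, dark, cal, cald)$reflectance
  }
  expect_equal(build(1), build(7.3), tolerance = 1e-12)
})

test_that("wavelengths without calibration signal are masked, not divided", {
  R_true <- rep(0.2, length(wl))
  cal_counts <- resp * 100
  dead <- wl > 740
  cal_counts[dead] <- 0
  raw <- mk(R_true * resp * 50, 50)
  dark <- mk(rep(0, length(wl)), 50, kind = "dark")
  cal <- mk(cal_counts, 100, kind = "calibration")
  cald <- mk(rep(0, length(wl)), 100, kind = "calibration_dark")
  cs <- correct_spectrum(raw, dark, cal, cald)
  expect_true(all(cs$mask[dead]))
  expect_true(all(is.na(cs$reflectance[dead])))
  expect_true(all(!cs$mask[!dead]))
  # a calibration below the noise floor everywhere is unusable
  cal0 <- mk(rep(0, length(wl)), 100, kind = "calibration")
  expect_error(correct_spectrum(raw, dark, cal0, cald),
               class = "drsfit_unusable_fiber")
})

test_that("adaptive integration-time rule targets half dynamic range", {
  counts <- 2000 * exp(-0.5 * ((wl - 600) / 80)^2) + 50
  raw <- mk(counts, 25)
  t_new <- select_integration_time(raw, 50)
  # re-measuring at t_new puts the dark-subtracted peak at DR/2
  peak_rescaled <- max(counts - 50) * t_new / 25
  expect_equal(peak_rescaled, 0.5 * 65535, tolerance = 1e-10)
  # clipping at both bounds
  expect_equal(select_integration_time(mk(counts, 0.001), 50), 10)
  expect_equal(select_integration_time(mk(counts / 1e4 + 50, 5000), 50), 5000)
  # saturation must signal re-measurement, not silently proceed
  expect_error(select_integration_time(mk(pmin(counts * 100, 65535), 25), 50),
               class = "drsfit_saturated")
})

test_that("detector QC keeps good fibers and rejects failure modes", {
  st <- list(conc = c(HbO2 = 20, Hb = 20, MBmono = 5, MBdimer = 1),
             a = 8, b = 1.2)
  tr <- structure(list(subject = "QC", pre = st, post = st,
                       bad_fibers = c(2L, 5L), snr = 100, seed = 31L),
                  class = "subject_truth")
  mset <- simulate_measurement(tr, "post", tl_lut, tl_basis)
  cal <- calibrate_measurement(mset)
  expect_identical(detector_qc(cal), setdiff(1:8, c(2L, 5L)))
  tr$bad_fibers <- 1:5
  mset2 <- simulate_measurement(tr, "post", tl_lut, tl_basis)
  expect_error(detector_qc(calibrate_measurement(mset2)),
               class = "drsfit_insufficient_fibers")
})

test_that("measurement sets round-trip through text serialization", {
  mset <- noise_free_set(c(HbO2 = 15, Hb = 25, MBmono = 2, MBdimer = 0.5),
                         a = 7, b = 1.0)
  dir <- tempfile("mset")
  manifest <- write_measurement_set(mset, dir)
  back <- read_measurement_set(manifest)
  expect_equal(length(back$fibers), length(mset$fibers))
  expect_equal(back$condition, mset$condition)
  for (k in seq_along(mset$fibers)) {
    expect_equal(back$fibers[[k]]$raw$counts, mset$fibers[[k]]$raw$counts)
    expect_equal(back$fibers[[k]]$cal$integration_time_ms,
                 mset$fibers[[k]]$cal$integration_time_ms)
  }
  unlink(dir, recursive = TRUE)
})
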