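test_that("SRSE matches its closed forms on small matrices", {
  m <- matrix(c(1, 2, 3, 4), 2, 2)
  p <- matrix(c(1, 0, 0, 4), 2, 2)
  # per-fiber roots: sqrt(0 + 4) and sqrt(9 + 0)
  expect_equal(compute_srse(m, p, "sum_of_root"), 2 + 3)
  expect_equal(compute_srse(m, p, "root_of_sum"), sqrt(13))
  expect_equal(compute_srse(m, m), 0)
  expect_error(compute_srse(m, p[1, , drop = FALSE]), "equal shape")
})

test_that("forward spectra require on-grid wavelengths", {
  expect_error(
    forward_spectra(c(HbO2 = 1, Hb = 1, MBmono = 0, MBdimer = 0), 8, 1,
                    tl_lut, tl_basis, wavelengths = c(550.5, 600.5)),
    "basis grid")
})

truth_conc <- c(HbO2 = 25, Hb = 35, MBmono = 5, MBdimer = 1.5)
truth_a <- 8.4; truth_b <- 1.2
nf_set <- noise_free_set(truth_conc, truth_a, truth_b, seed = 7L)
fit_full <- drs_fit(nf_set, tl_lut, tl_basis,
                    config = fit_config(mode = "post", seed = 2))

test_that("noise-free synthetic data are recovered essentially exactly", {
  cf <- coef(fit_full)
  expect_equal(unname(cf[names(truth_conc)]), unname(truth_conc),
               tolerance = 1e-4)
  expect_equal(cf[["a"]], truth_a, tolerance = 1e-5)
  expect_equal(cf[["b"]], truth_b, tolerance = 1e-4)
  expect_lt(fit_full$srse, 1e-6)
  expect_false(fit_full$convergence$flagged)
})

test_that("fit object methods are coherent", {
  expect_s3_class(fit_full, "drs_fit")
  expect_equal(dim(residuals(fit_full)),
               c(length(fit_full$wavelengths), length(fit_full$fibers)))
  expect_equal(fitted(fit_full) + residuals(fit_full), fit_full$measured)
  expect_equal(predict(fit_full), fit_full$predicted, tolerance = 1e-12)
  rec <- summarize_fit(fit_full)
  expect_equal(rec$mb, compute_total_mb(coef(fit_full)[1:4]))
  expect_equal(rec$so2, compute_so2(coef(fit_full)[1:4]))
  expect_output(print(fit_full), "SRSE")
  expect_output(print(summary(fit_full)), "Convergence")
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit_full); grDevices::dev.off()
  expect_true(file.exists(f)); unlink(f)
  sims <- simulate(fit_full, nsim = 2, seed = 3L)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "measurement_set")
})

test_that("restricting the model can only worsen the misfit", {
  fit_pre <- drs_fit(nf_set, tl_lut, tl_basis,
                     config = fit_config(mode = "pre", seed = 2))
  fit_nodim <- drs_fit(nf_set, tl_lut, tl_basis,
                       config = fit_config(mode = "post",
                                           include_dimer = FALSE, seed = 2))
  expect_gt(fit_pre$srse, fit_nodim$srse)
  expect_gte(fit_nodim$srse, fit_full$srse)
  expect_equal(coef(fit_pre)[["MBmono"]], 0)
  expect_equal(coef(fit_nodim)[["MBdimer"]], 0)
})

test_that("estimates are stable under a fiber subset", {
  fit5 <- drs_fit(nf_set, tl_lut, tl_basis,
                  config = fit_config(mode = "post", seed = 9),
                  fibers = 1:5)
  expect_equal(fit5$mb_total, fit_full$mb_total, tolerance = 0.02)
  expect_equal(fit5$musp665, fit_full$musp665, tolerance = 0.02)
  expect_error(drs_fit(nf_set, tl_lut, tl_basis, fibers = 1:3),
               class = "drsfit_insufficient_fibers")
})
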