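test_that("interpolation is exact at grid nodes", {
  i <- c(2, 10, 30); j <- c(1, 12, 26); k <- 3
  for (t in seq_along(i)) {
    expect_equal(
      lut_reflectance(tl_lut, tl_lut$mua_grid[i[t]],
                      tl_lut$musp_grid[j[t]], k),
      tl_lut$reflectance[i[t], j[t], k], tolerance = 1e-12,
      ignore_attr = TRUE)
  }
})

test_that("queries outside the hull raise drsfit_out_of_range", {
  expect_error(lut_reflectance(tl_lut, 100, 10, 1),
               class = "drsfit_out_of_range")
  expect_error(lut_reflectance(tl_lut, 1, 0.5, 1),
               class = "drsfit_out_of_range")
  expect_error(lut_reflectance(tl_lut, -0.1, 10, 1),
               class = "drsfit_out_of_range")
})

test_that("separations match by index or physical value", {
  sep_cm <- tl_geom$separations_cm[4]
  expect_equal(lut_reflectance(tl_lut, 1, 10, 4),
               lut_reflectance(tl_lut, 1, 10, sep_cm))
  expect_error(lut_reflectance(tl_lut, 1, 10, 0.9999), "does not match")
})

test_that("interpolated reflectance is monotone in absorption", {
  mua <- seq(0.01, 60, length.out = 120)
  for (k in c(1, 5, 8)) {
    R <- lut_reflectance(tl_lut, mua, rep(9.3, length(mua)), k)
    expect_true(all(diff(R) < 0))
  }
})

test_that("tables rebuild identically from the same seed and survive JSON", {
  st <- mc_settings(n_photons = 5e3, seed = 42)
  mini <- function() build_lut(musp_grid = c(8, 10, 12),
                               mua_grid = c(0, 0.1, 1, 10),
                               geometry = tl_geom, settings = st)
  l1 <- mini(); l2 <- mini()
  expect_identical(l1$reflectance, l2$reflectance)
  f <- tempfile(fileext = ".json")
  write_lut(l1, f)
  l3 <- read_lut(f)
  expect_equal(l3$reflectance, l1$reflectance, tolerance = 1e-14)
  expect_equal(l3$mua_grid, l1$mua_grid)
  expect_equal(l3$geometry$separations_cm, l1$geometry$separations_cm)
  unlink(f)
})

test_that("absorption-grid refinement converges to the exact rescaled value", {
  # one white run provides both the exact off-grid reference and the table
  # columns, so the only error is interpolation error
  st <- mc_settings(n_photons = 2e4, seed = 9)
  run <- run_photon_mc(0, 10, tl_geom, st, record_paths = TRUE)
  prep <- prepare_rescale(run$records)
  lut_from <- function(n_mua) {
    grid <- c(0, 10^seq(log10(1e-3), log10(80), length.out = n_mua))
    structure(list(mua_grid = grid, musp_grid = c(9, 10, 11),
                   reflectance = {
                     arr <- array(NA_real_, c(length(grid), 3, 8))
                     col <- rescale_white_mc(prep, grid)
                     # queries sit exactly on the middle scattering node, so
                     # the outer columns never enter the interpolation
                     for (j in 1:3) arr[, j, ] <- col
                     arr
                   },
                   geometry = tl_geom, settings = st, u0 = 0.01),
              class = "reflectance_lut")
  }
  mua_q <- c(0.0567, 0.789, 7.89, 33.3)
  exact <- sapply(mua_q, function(m) rescale_white_mc(prep, m)$reflectance[2])
  err <- sapply(c(11, 22, 44), function(n) {
    lut_n <- lut_from(n)
    approxed <- sapply(mua_q, function(m) lut_reflectance(lut_n, m, 10, 2))
    max(abs(approxed / exact - 1))
  })
  expect_true(all(diff(err) < 1e-12))        # error shrinks with refinement
  expect_lt(err[3], 0.015)                   # production grid: ~1% error
})
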