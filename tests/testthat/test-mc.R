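small_mc <- mc_settings(n_photons = 2e4, seed = 11)

test_that("energy ledger balances exactly and runs are deterministic", {
  for (pars in list(c(0.5, 10), c(5, 5), c(0, 12))) {
    run <- run_photon_mc(pars[1], pars[2], tl_geom, small_mc)
    expect_lt(abs(sum(run$ledger) - 1), 1e-10)
    # "terminated" is a net balance (roulette kills minus survivor boosts
    # plus path-cap kills) and may dip below zero in a finite sample
    expect_true(all(run$ledger[c("specular", "diffuse", "absorbed")] >= 0))
  }
  r1 <- run_photon_mc(1, 10, tl_geom, small_mc)
  r2 <- run_photon_mc(1, 10, tl_geom, small_mc)
  expect_identical(r1$reflectance, r2$reflectance)
  r3 <- run_photon_mc(1, 10, tl_geom, mc_settings(n_photons = 2e4, seed = 12))
  expect_false(identical(r1$reflectance, r3$reflectance))
})

test_that("non-absorbing index-matched medium returns all photons", {
  # unity albedo: nothing is absorbed; everything either exits diffusely or
  # is terminated by the path cap / roulette bookkeeping
  run <- run_photon_mc(0, 10, tl_geom,
                       mc_settings(n_photons = 1e4, seed = 3,
                                   max_path_cm = 500),
                       full_acceptance = TRUE, index_matched = TRUE)
  expect_equal(unname(run$ledger[["absorbed"]]), 0)
  expect_equal(unname(run$ledger[["specular"]]), 0)
  expect_gt(run$ledger[["diffuse"]], 0.95)
})

test_that("arc-fraction detector weight matches numerical integration", {
  a <- 0.01                                  # detector radius, cm
  d <- 0.05                                  # detector center distance
  # numerical reference: fraction of the circle of radius r inside the
  # disk (midpoint rule, so the indicator's endpoints are unbiased)
  num_frac <- function(r) {
    n <- 2e5
    th <- (seq_len(n) - 0.5) * pi / n
    mean(sqrt(r^2 + d^2 - 2 * r * d * cos(th)) <= a)
  }
  for (r in c(0.041, 0.05, 0.0599)) {
    expect_equal(drsfit:::arc_fraction_cpp(r, d, a), num_frac(r),
                 tolerance = 1e-3)
  }
  expect_equal(drsfit:::arc_fraction_cpp(0.01, 0.05, a), 0)  # fully outside
  expect_equal(drsfit:::arc_fraction_cpp(0.001, 0.005, 0.01), 1) # inside
})

test_that("white rescaling reproduces the zero-absorption run exactly", {
  run <- run_photon_mc(0, 10, tl_geom, small_mc, record_paths = TRUE)
  resc <- rescale_white_mc(run$records, 0)
  expect_equal(resc$reflectance, run$reflectance, tolerance = 1e-12)
})

test_that("rescaled reflectance decreases monotonically with absorption", {
  run <- run_photon_mc(0, 10, tl_geom, small_mc, record_paths = TRUE)
  mua <- c(0, 0.1, 0.5, 1, 5, 20, 60)
  R <- rescale_white_mc(run$records, mua)
  expect_true(all(apply(R, 2, function(col) all(diff(col) < 0))))
})

test_that("white rescaling agrees with a direct absorbing run", {
  white <- run_photon_mc(0, 10, tl_geom, small_mc, record_paths = TRUE)
  resc <- rescale_white_mc(white$records, 0.5)
  direct <- run_photon_mc(0.5, 10, tl_geom,
                          mc_settings(n_photons = 2e4, seed = 77))
  z <- (resc$reflectance - direct$reflectance) /
    sqrt(resc$se^2 + direct$se^2)
  expect_true(all(abs(z) < 3))
})

test_that("rescaling refuses records not generated at zero absorption", {
  run <- run_photon_mc(0.5, 10, tl_geom, small_mc, record_paths = TRUE)
  expect_error(rescale_white_mc(run$records, 1), "mua = 0")
})

test_that("reflectance decays with detector separation", {
  run <- run_photon_mc(0.5, 10, tl_geom,
                       mc_settings(n_photons = 5e4, seed = 21))
  # adjacent fibers can invert within Monte Carlo noise; compare fibers
  # several separations apart, where the decay dominates the noise
  r <- run$reflectance
  expect_gt(r[1], r[4])
  expect_gt(r[4], r[8])
  expect_lt(cor(seq_along(r), r, method = "spearman"), -0.8)
})
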