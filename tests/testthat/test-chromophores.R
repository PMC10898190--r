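test_that("wavelength grids validate range, spacing and 665 nm coverage", {
  g <- wavelength_grid()
  expect_s3_class(g, "wavelength_grid")
  expect_true(665 %in% as.numeric(g))
  expect_error(as_wavelength_grid(c(500, 400)), "increasing")
  expect_error(as_wavelength_grid(seq(450, 750, by = 5)), "spacing")
  expect_error(as_wavelength_grid(seq(450, 600, by = 1)), "665")
})

test_that("synthetic basis has the documented band structure", {
  wl <- as.numeric(tl_basis$wavelength)
  eps <- tl_basis$epsilon
  expect_identical(colnames(eps), c("HbO2", "Hb", "MBmono", "MBdimer"))
  expect_true(all(eps >= 0))
  # band maxima at the documented locations (within the red/Q-band window)
  peak_at <- function(col, lo, hi) {
    sel <- wl >= lo & wl <= hi
    wl[sel][which.max(eps[sel, col])]
  }
  expect_equal(peak_at("HbO2", 560, 600), 577, tolerance = 0.01)
  expect_equal(peak_at("HbO2", 500, 560), 542, tolerance = 0.01)
  expect_equal(peak_at("Hb", 500, 600), 556, tolerance = 0.01)
  expect_equal(peak_at("MBmono", 620, 750), 664, tolerance = 0.01)
  expect_equal(peak_at("MBdimer", 550, 650), 600, tolerance = 0.01)
  # MB monomer dominates hemoglobin per uM at the 665 nm treatment line
  i665 <- match(665, wl)
  expect_gt(eps[i665, "MBmono"], 10 * eps[i665, "HbO2"])
})

test_that("compose_mua is linear in concentrations and checks grids", {
  c1 <- c(HbO2 = 10, Hb = 20, MBmono = 3, MBdimer = 1)
  c2 <- c(HbO2 = 5, Hb = 0, MBmono = 0, MBdimer = 2)
  expect_equal(compose_mua(c1 + c2, tl_basis),
               compose_mua(c1, tl_basis) + compose_mua(c2, tl_basis))
  expect_equal(compose_mua(0 * c1, tl_basis),
               rep(0, length(tl_basis$wavelength)),
               ignore_attr = TRUE)
  expect_error(compose_mua(c1, tl_basis, grid = wavelength_grid(500, 740)),
               "mismatch")
  expect_error(compose_mua(c(HbO2 = -1, Hb = 0, MBmono = 0, MBdimer = 0),
                           tl_basis), "nonnegative")
})

test_that("power-law scattering is anchored at 665 nm", {
  g <- wavelength_grid()
  m <- compose_musp(8, 1.2, g)
  expect_equal(m[match(665, as.numeric(g))], 8)
  expect_true(all(diff(m) < 0))              # decreasing for b > 0
  expect_equal(compose_musp(8, 0, g), rep(8, length(g)))
  expect_error(compose_musp(-1, 1, g), "positive")
})

test_that("SO2 and total-MB reporting rules", {
  conc <- c(HbO2 = 30, Hb = 10, MBmono = 4, MBdimer = 2)
  expect_equal(compute_so2(conc), 75)
  expect_warning(so2 <- compute_so2(c(HbO2 = 0, Hb = 0, MBmono = 1,
                                      MBdimer = 0)),
                 class = "drsfit_undefined_so2")
  expect_identical(so2, NA_real_)
  expect_equal(compute_total_mb(conc), 8)                 # mono + 2 dimer
  expect_equal(compute_total_mb(conc, rule = "amplitude_sum"), 6)
})

test_that("a basis written as CSV tables reads back equal", {
  dir <- withr_like_tempdir <- tempfile("basis")
  dir.create(dir)
  files <- sapply(c("HbO2", "Hb", "MBmono", "MBdimer"), function(nm) {
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(data.frame(wavelength_nm = as.numeric(tl_basis$wavelength),
                                epsilon = tl_basis$epsilon[, nm]),
                     f, row.names = FALSE)
    f
  })
  b2 <- read_chromophore_basis(files)
  expect_equal(b2$epsilon, tl_basis$epsilon, tolerance = 1e-12)
  expect_error(read_chromophore_basis(files[1:3]), "named")
  unlink(dir, recursive = TRUE)
})
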