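# Shared fixtures, built once per test run.  The lookup table uses a
# reduced photon count: adequate because the same table generates and fits
# the synthetic round trips, so its Monte Carlo noise cancels there, while
# the transport-physics tests carry their own standard-error budgets.
tl_basis <- chromophore_basis()
tl_geom <- probe_geometry()
tl_settings <- mc_settings(n_photons = 3e4, seed = 5)
tl_lut <- build_lut(geometry = tl_geom, settings = tl_settings)

# Farrell, Patterson & Wilson (1992) two-source diffusion-theory
# reflectance for a semi-infinite medium, matched boundary (A = 1).
# Independent oracle for the Monte Carlo kernel: valid when musp >> mua
# and rho is several transport mean free paths.
diffusion_reflectance <- function(mua, musp, rho) {
  mutp <- mua + musp
  D <- 1 / (3 * mutp)
  mueff <- sqrt(mua / D)
  z0 <- 1 / mutp
  zb <- 2 * D            # A = 1
  r1 <- sqrt(z0^2 + rho^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho^2)
  (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
     (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2) / (4 * pi)
}

# noise-free synthetic measurement for a plain truth list
noise_free_set <- function(conc, a, b, condition = "post", seed = 1L) {
  simulate_measurement(list(conc = conc, a = a, b = b),
                       condition = condition, lut = tl_lut,
                       basis = tl_basis, snr = Inf, seed = seed)
}
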