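#' Configuration for the multispectral inversion
#'
#' @param band Wavelength fit band, nm; must lie inside the chromophore
#'   basis grid and the lookup-table validity range.
#' @param mode `"post"` fits all four absorbers; `"pre"` fixes both
#'   methylene blue amplitudes at zero (no MB present before infusion).
#' @param include_dimer Include the MB dimer term (`"post"` mode only);
#'   switching it off reproduces the dimer-free model variant.
#' @param multistart Number of seeded Latin-hypercube starting points
#'   (>= 1).
#' @param seed RNG seed for the multistart design.
#' @param conc_max Upper concentration bounds, uM.
#' @param a_bounds,b_bounds Bounds for the power-law scattering amplitude
#'   (cm^-1) and power.
#' @param weighted Weight residuals by the per-wavelength noise estimate
#'   when available.
#' @param srse SRSE variant: `"sum_of_root"` (sum over fibers of the root
#'   of the per-fiber squared-error sum, the default reading) or
#'   `"root_of_sum"`.
#' @param maxiter Optimizer iteration cap per start.
#' @param refine Run a second multistart wave (full bound box plus
#'   jittered copies of the interim best) when the best first-wave
#'   solution still misfits the data by far more than the noise allows.
#' @return Object of class `fit_config`.
#' @export
fit_config <- function(band = c(500, 740), mode = c("post", "pre"),
                       include_dimer = TRUE, multistart = 8L, seed = 1L,
                       conc_max = c(HbO2 = 500, Hb = 500, MBmono = 400,
                                    MBdimer = 200),
                       a_bounds = c(1, 25), b_bounds = c(-2, 4),
                       weighted = TRUE,
                       srse = c("sum_of_root", "root_of_sum"),
                       maxiter = 150L, refine = TRUE) {
  mode <- match.arg(mode)
  srse <- match.arg(srse)
  if (multistart < 1L) stop("multistart must be >= 1", call. = FALSE)
  structure(list(band = band, mode = mode, include_dimer = include_dimer,
                 multistart = as.integer(multistart), seed = as.integer(seed),
                 conc_max = conc_max, a_bounds = a_bounds,
                 b_bounds = b_bounds, weighted = weighted, srse = srse,
                 maxiter = as.integer(maxiter), refine = isTRUE(refine)),
            class = "fit_config")
}

#' Predict per-fiber reflectance spectra from model parameters
#'
#' Composes the absorption spectrum from chromophore concentrations and the
#' power-law reduced scattering spectrum, then interpolates the lookup
#' table at every wavelength for each requested detector separation.
#'
#' @param conc Named concentrations, uM (see [compose_mua()]).
#' @param a,b Power-law scattering parameters (mu_s' at 665 nm, power).
#' @param lut A [build_lut()] reflectance table.
#' @param basis A [chromophore_basis()].
#' @param wavelengths Wavelengths at which to predict (subset of the basis
#'   grid), nm.
#' @param fibers Detector indices to predict (default all).
#' @return Matrix `length(wavelengths) x length(fibers)` of reflectance.
#' @export
forward_spectra <- function(conc, a, b, lut, basis,
                            wavelengths = as.numeric(basis$wavelength),
                            fibers = seq_along(lut$geometry$separations_cm)) {
  idx <- match(round(wavelengths, 6), round(as.numeric(basis$wavelength), 6))
  if (anyNA(idx)) {
    stop("wavelengths must lie on the chromophore basis grid", call. = FALSE)
  }
  mua <- drop(basis$epsilon[idx, , drop = FALSE] %*% as_conc(conc))
  musp <- compose_musp(a, b, wavelengths)
  out <- sapply(fibers, function(k) lut_reflectance(lut, mua, musp, k))
  matrix(out, nrow = length(wavelengths),
         dimnames = list(NULL, paste0("fiber", fibers)))
}

#' Sum of root squared error across detector fibers
#'
#' Fit-quality metric: for each fiber the root of the sum over wavelengths
#' of squared differences between measured and predicted reflectance, summed
#' over fibers (`variant = "sum_of_root"`).  The alternative
#' `"root_of_sum"` takes a single root over everything.
#'
#' @param measured,predicted Matrices (wavelength x fiber) on one grid.
#' @param variant Formula variant.
#' @return Nonnegative scalar (calibrated-reflectance units).
#' @export
compute_srse <- function(measured, predicted,
                         variant = c("sum_of_root", "root_of_sum")) {
  variant <- match.arg(variant)
  measured <- as.matrix(measured); predicted <- as.matrix(predicted)
  if (!all(dim(measured) == dim(predicted)) || length(measured) == 0L) {
    stop("measured and predicted must be nonempty matrices of equal shape",
         call. = FALSE)
  }
  d2 <- (measured - predicted)^2
  if (variant == "sum_of_root") {
    sum(sqrt(colSums(d2, na.rm = TRUE)))
  } else {
    sqrt(sum(d2, na.rm = TRUE))
  }
}

# seeded package functions must not disturb the caller's RNG stream:
# capture .Random.seed before set.seed() and restore it on exit
save_rng <- function() {
  get0(".Random.seed", envir = globalenv(), inherits = FALSE)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# parameter bookkeeping: full vector is (HbO2, Hb, MBmono, MBdimer, a, b);
# mode/include_dimer decide which entries are free
free_params <- function(config) {
  free <- c(HbO2 = TRUE, Hb = TRUE,
            MBmono = config$mode == "post",
            MBdimer = config$mode == "post" && config$include_dimer,
            a = TRUE, b = TRUE)
  names(free) <- c(chromophore_names, "a", "b")
  free
}

param_bounds <- function(config) {
  lower <- c(rep(0, 4), config$a_bounds[1], config$b_bounds[1])
  upper <- c(config$conc_max[chromophore_names], config$a_bounds[2],
             config$b_bounds[2])
  names(lower) <- names(upper) <- c(chromophore_names, "a", "b")
  list(lower = lower, upper = upper)
}

# crude linearized start for the hemoglobin amplitudes: apparent absorbance
# relative to the zero-absorption prediction at two wavelengths bracketing
# the Hb/HbO2 crossover, solved as a 2x2 linear system; falls back to NULL
# when degenerate
hb_start_heuristic <- function(y, wavelengths, fibers, lut, basis, config) {
  lam <- c(560, 600)
  idx <- vapply(lam, function(l) which.min(abs(wavelengths - l)), 0L)
  if (any(abs(wavelengths[idx] - lam) > 5)) return(NULL)
  a0 <- mean(config$a_bounds); b0 <- 1
  out <- tryCatch({
    r0 <- forward_spectra(c(HbO2 = 0, Hb = 0, MBmono = 0, MBdimer = 0),
                          a0, b0, lut, basis,
                          wavelengths = wavelengths[idx], fibers = fibers)
    appA <- -log(pmax(y[idx, , drop = FALSE] / r0, 1e-12))
    # mean apparent absorbance over fibers, scaled by a nominal path factor
    pathf <- 2 * mean(lut$geometry$separations_cm)
    mua_hat <- rowMeans(appA) / pathf
    E <- basis$epsilon[match(round(wavelengths[idx], 6),
                             round(as.numeric(basis$wavelength), 6)),
                       c("HbO2", "Hb")]
    sol <- solve(E, mua_hat)
    if (any(!is.finite(sol)) || any(sol < 0)) return(NULL)
    pmin(sol, config$conc_max[c("HbO2", "Hb")] * 0.9)
  }, error = function(e) NULL)
  out
}

#' Fit abscess-wall optical properties and chromophore concentrations
#'
#' The core estimator: bound-constrained nonlinear least squares of the
#' lookup-table forward model to calibrated reflectance spectra across all
#' usable detector fibers jointly, over chromophore concentrations
#' (oxy/deoxy-hemoglobin and, in `"post"` mode, MB monomer/dimer) and the
#' power-law scattering parameters `a`, `b`.  Multiple seeded
#' Latin-hypercube starting points guard against local minima; the best
#' solution by residual sum of squares is returned.
#'
#' Optical-property spectra that wander outside the lookup-table hull
#' during the search are clamped, with a smooth penalty added to the
#' residuals so the optimizer is driven back inside.
#'
#' @param cal_set A [calibrate_measurement()] result (or a
#'   [measurement_set()], which is calibrated first).
#' @param lut A [build_lut()] reflectance table.
#' @param basis A [chromophore_basis()].
#' @param config A [fit_config()].
#' @param fibers Usable fiber indices; default runs [detector_qc()].
#' @param qc_args List of extra arguments for [detector_qc()].
#' @return Object of class `drs_fit` with components `coefficients`
#'   (HbO2, Hb, MBmono, MBdimer in uM; `a` in cm^-1; `b`), `so2` (%),
#'   `mb_total` (uM), `mua665`, `musp665` (cm^-1), `srse`, `ssr`,
#'   `fibers`, `wavelengths`, `measured`, `predicted`, `noise`,
#'   `convergence`, plus the inputs needed by the methods.
#' @seealso [summary.drs_fit()], [predict.drs_fit()], [plot.drs_fit()],
#'   [summarize_fit()]
#' @export
drs_fit <- function(cal_set, lut, basis, config = fit_config(),
                    fibers = NULL, qc_args = list()) {
  if (inherits(cal_set, "measurement_set")) {
    cal_set <- calibrate_measurement(cal_set)
  }
  stopifnot(inherits(cal_set, "calibrated_set"),
            inherits(lut, "reflectance_lut"),
            inherits(basis, "chromophore_basis"),
            inherits(config, "fit_config"))
  if (is.null(fibers)) {
    fibers <- do.call(detector_qc, c(list(cal_set), qc_args))
  }
  if (length(fibers) < 4L) {
    stop(errorCondition("fewer than 4 usable detector fibers",
                        class = "drsfit_insufficient_fibers"))
  }

  bg <- as.numeric(basis$wavelength)
  band_w <- bg[bg >= config$band[1] & bg <= config$band[2]]
  # assemble measured matrix on the basis grid, restricted to the fit band
  y <- sapply(fibers, function(i) {
    cs <- cal_set$spectra[[i]]
    stats::approx(cs$wavelength, cs$reflectance, xout = band_w, rule = 1)$y
  })
  nz <- sapply(fibers, function(i) {
    cs <- cal_set$spectra[[i]]
    stats::approx(cs$wavelength, cs$noise, xout = band_w, rule = 1)$y
  })
  keep <- rowSums(!is.finite(y)) == 0
  y <- y[keep, , drop = FALSE]; nz <- nz[keep, , drop = FALSE]
  colnames(y) <- colnames(nz) <- paste0("fiber", fibers)
  wl <- band_w[keep]
  if (length(wl) < 20L) stop("too few usable wavelengths in fit band",
                             call. = FALSE)
  wts <- if (config$weighted && all(is.finite(nz)) && all(nz > 0)) {
    1 / nz
  } else {
    matrix(1, nrow(y), ncol(y))
  }

  eps_band <- basis$epsilon[match(round(wl, 6), round(bg, 6)), , drop = FALSE]
  lam_ratio <- wl / 665
  mua_max <- max(lut$mua_grid); musp_rng <- range(lut$musp_grid)
  seps <- fibers

  residual_fn <- function(par) {
    conc <- pmax(par[chromophore_names], 0)
    mua <- drop(eps_band %*% conc)
    musp <- par[["a"]] * lam_ratio^(-par[["b"]])
    # clamp into the LUT hull with a penalty proportional to the excess
    pen <- numeric(0)
    over_a <- mua > mua_max
    if (any(over_a)) {
      pen <- c(pen, 5 * (mua[over_a] / mua_max - 1))
      mua[over_a] <- mua_max
    }
    lo_s <- musp < musp_rng[1]; hi_s <- musp > musp_rng[2]
    if (any(lo_s)) {
      pen <- c(pen, 5 * (musp_rng[1] / musp[lo_s] - 1))
      musp[lo_s] <- musp_rng[1]
    }
    if (any(hi_s)) {
      pen <- c(pen, 5 * (musp[hi_s] / musp_rng[2] - 1))
      musp[hi_s] <- musp_rng[2]
    }
    pred <- sapply(seps, function(k) lut_reflectance(lut, mua, musp, k))
    c(as.numeric((y - pred) * wts), pen)
  }

  free <- free_params(config)
  bounds <- param_bounds(config)
  npar <- sum(free)
  old_rng <- save_rng()
  on.exit(restore_rng(old_rng), add = TRUE)
  set.seed(config$seed)
  lhs_starts <- function(n, lo, hi) {
    H <- lhs::randomLHS(n, npar)
    lapply(seq_len(n), function(i) {
      stats::setNames(lo[free] + H[i, ] * (hi[free] - lo[free]),
                      names(free)[free])
    })
  }
  # first wave: Latin-hypercube starts over a plausible sub-box of the
  # bounds (where clinical values concentrate), plus a linearized
  # hemoglobin start
  start_lo <- c(HbO2 = 0, Hb = 0, MBmono = 0, MBdimer = 0,
                a = max(bounds$lower[["a"]], 3), b = 0.2)
  start_hi <- c(HbO2 = 120, Hb = 120, MBmono = 80, MBdimer = 40,
                a = min(bounds$upper[["a"]], 16), b = 2.2)
  starts <- lhs_starts(config$multistart, start_lo, start_hi)
  hb0 <- hb_start_heuristic(y, wl, fibers, lut, basis, config)
  if (!is.null(hb0)) {
    p <- starts[[1]]
    p[intersect(names(p), c("HbO2", "Hb"))] <-
      hb0[intersect(names(p), c("HbO2", "Hb"))]
    starts <- c(starts, list(p))
  }

  full_par <- function(p) {
    out <- c(HbO2 = 0, Hb = 0, MBmono = 0, MBdimer = 0, a = NA_real_,
             b = NA_real_)
    out[names(p)] <- p
    out
  }
  best <- NULL; n_ok <- 0L; n_starts <- 0L
  run_starts <- function(start_list) {
    for (p0 in start_list) {
      n_starts <<- n_starts + 1L
      fitk <- tryCatch(
        minpack.lm::nls.lm(
          par = p0,
          lower = bounds$lower[names(p0)], upper = bounds$upper[names(p0)],
          fn = function(p) residual_fn(full_par(p)),
          control = minpack.lm::nls.lm.control(maxiter = config$maxiter,
                                               ftol = 1e-12, ptol = 1e-12)),
        error = function(e) NULL)
      if (is.null(fitk)) next
      if (fitk$info %in% c(1, 2, 3, 4)) n_ok <<- n_ok + 1L
      if (is.null(best) || fitk$deviance < best$deviance) best <<- fitk
    }
  }
  run_starts(starts)
  if (is.null(best)) {
    stop("optimization failed from every starting point", call. = FALSE)
  }
  # refinement wave: if the best solution still misfits the data by far
  # more than the noise allows, the search is stuck in a local minimum;
  # retry from a Latin hypercube over the full bound box plus jittered
  # copies of the current best
  misfit <- best$deviance / length(y)
  poor <- if (config$weighted && all(is.finite(nz)) && all(nz > 0)) {
    misfit > 10                      # residuals are in noise-sigma units
  } else {
    misfit > (0.05 * mean(abs(y)))^2 # RMS misfit above 5% of mean signal
  }
  if (isTRUE(config$refine) && poor) {
    wide <- lhs_starts(config$multistart,
                       bounds$lower + 1e-3 * (bounds$upper - bounds$lower),
                       bounds$upper)
    p_best <- stats::setNames(best$par, names(starts[[1]]))
    jitter <- lapply(1:4, function(i) {
      p <- p_best * exp(stats::rnorm(length(p_best), 0, 0.4))
      pmin(pmax(p, bounds$lower[names(p)]), bounds$upper[names(p)])
    })
    run_starts(c(wide, jitter))
  }
  flagged <- n_ok == 0L
  if (flagged) {
    warning(warningCondition(
      "no multistart run satisfied the convergence test; result flagged",
      class = "drsfit_nonconvergence"))
  }

  cf <- full_par(stats::setNames(best$par, names(starts[[1]])))
  conc <- cf[chromophore_names]
  pred <- forward_spectra(conc, cf[["a"]], cf[["b"]], lut, basis,
                          wavelengths = wl, fibers = fibers)
  so2 <- if (sum(conc[c("HbO2", "Hb")]) > 0) {
    compute_so2(conc)
  } else {
    NA_real_
  }
  res <- structure(list(
    coefficients = cf,
    so2 = so2,
    mb_total = compute_total_mb(conc),
    mua665 = drop(basis_eps665(basis) %*% conc),
    musp665 = cf[["a"]],
    srse = compute_srse(y, pred, variant = config$srse),
    ssr = best$deviance,
    fibers = fibers,
    wavelengths = wl,
    measured = y,
    predicted = pred,
    noise = nz,
    convergence = list(flagged = flagged, n_converged = n_ok,
                       n_starts = n_starts, info = best$info,
                       message = best$message,
                       iterations = best$niter),
    subject = cal_set$subject,
    condition = cal_set$condition,
    config = config, lut = lut, basis = basis), class = "drs_fit")
  res
}

#' Table-style one-row summary of a fit
#'
#' Emits the reporting quantities at 665 nm: absorption and reduced
#' scattering coefficients (cm^-1), oxygen saturation (%), total MB (uM),
#' plus SRSE and the number of fibers used.  An undefined SO2 propagates as
#' `NA`.
#'
#' @param result A [drs_fit()] result.
#' @return One-row `data.frame`.
#' @export
summarize_fit <- function(result) {
  stopifnot(inherits(result, "drs_fit"))
  data.frame(subject = result$subject, condition = result$condition,
             mua665 = result$mua665, musp665 = result$musp665,
             so2 = result$so2, mb = result$mb_total, srse = result$srse,
             n_fibers = length(result$fibers),
             flagged = result$convergence$flagged)
}

#' @export
print.drs_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Multispectral DRS fit (%s-MB%s), %d fibers, %d wavelengths\n",
              x$condition,
              if (identical(x$subject, NA_character_)) "" else
                paste0(", subject ", x$subject),
              length(x$fibers), length(x$wavelengths)))
  print(signif(x$coefficients, digits))
  cat(sprintf("mua(665) = %.3g cm^-1   musp(665) = %.3g cm^-1   SO2 = %s   [MB] = %.3g uM\n",
              x$mua665, x$musp665,
              if (is.na(x$so2)) "undefined" else sprintf("%.1f%%", x$so2),
              x$mb_total))
  cat(sprintf("SRSE = %.4g%s\n", x$srse,
              if (x$convergence$flagged) "   [non-convergent]" else ""))
  invisible(x)
}

#' @export
coef.drs_fit <- function(object, ...) object$coefficients

#' @export
fitted.drs_fit <- function(object, ...) object$predicted

#' @export
residuals.drs_fit <- function(object, ...) object$measured - object$predicted

#' Predicted reflectance spectra from a fitted model
#'
#' @param object A [drs_fit()] result.
#' @param wavelengths Wavelengths (on the basis grid) at which to predict;
#'   defaults to the fit band.
#' @param fibers Detector indices; defaults to the fibers used.
#' @param ... Unused.
#' @return Matrix of predicted reflectance (wavelength x fiber).
#' @export
predict.drs_fit <- function(object, wavelengths = object$wavelengths,
                            fibers = object$fibers, ...) {
  cf <- object$coefficients
  forward_spectra(cf[chromophore_names], cf[["a"]], cf[["b"]],
                  object$lut, object$basis, wavelengths = wavelengths,
                  fibers = fibers)
}

#' @export
summary.drs_fit <- function(object, ...) {
  out <- list(record = summarize_fit(object),
              coefficients = object$coefficients,
              convergence = object$convergence,
              srse = object$srse, fibers = object$fibers)
  class(out) <- "summary.drs_fit"
  out
}

#' @export
print.summary.drs_fit <- function(x, ...) {
  cat("Fitted chromophore concentrations (uM) and scattering parameters:\n")
  print(signif(x$coefficients, 4))
  cat("\nReporting quantities at 665 nm:\n")
  print(x$record, row.names = FALSE)
  cat(sprintf("\nConvergence: %d/%d starts converged (info %s, %d iterations)\n",
              x$convergence$n_converged, x$convergence$n_starts,
              x$convergence$info, x$convergence$iterations))
  invisible(x)
}

#' Plot measured and fitted reflectance spectra
#'
#' Measured calibrated reflectance as open circles and the fitted forward
#' model as solid lines, one color per detector fiber.
#'
#' @param x A [drs_fit()] result.
#' @param every Plot every `every`-th measured point (declutter).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.drs_fit <- function(x, every = 5L, ...) {
  wl <- x$wavelengths
  cols <- grDevices::hcl.colors(length(x$fibers), "Dark 3")
  sel <- seq(1, length(wl), by = every)
  graphics::matplot(wl[sel], x$measured[sel, , drop = FALSE], pch = 1,
                    col = cols, xlab = "wavelength (nm)",
                    ylab = "calibrated reflectance", ...)
  graphics::matlines(wl, x$predicted, lty = 1, col = cols)
  graphics::legend("topleft", bty = "n", col = cols, lty = 1,
                   legend = paste("fiber", x$fibers), cex = 0.8)
  invisible(x)
}
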