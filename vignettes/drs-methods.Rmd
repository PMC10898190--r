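---
title: "Methods: Monte Carlo lookup-table inversion of contact-probe diffuse reflectance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo lookup-table inversion of contact-probe diffuse reflectance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the model, the numerical choices and the
validation strategy behind **drsfit**, a package for estimating abscess
optical properties (absorption $\mu_a$ and reduced scattering $\mu_s'$),
tissue oxygen saturation (SO~2~) and methylene blue (MB) concentration
from spatially resolved diffuse reflectance spectra measured with a
multi-fiber surface-contact probe. None of the chunks are evaluated at
build time; every result shown in the README is reproduced by the code
printed here.

## 1. Physical model

### Probe geometry

The probe (`probe_geometry()`) holds one 200 µm source fiber and eight
200 µm detector fibers at center-to-center separations from 320 to
1310 µm, all with numerical aperture 0.22 behind a probe face of
refractive index 1.45 against tissue of index 1.37. Only the endpoint
separations are fixed by the instrument description; the interior
positions default to even spacing and should be replaced by probe
metrology when available.

### Photon transport

`run_photon_mc()` is a weighted photon Monte Carlo simulation of a
homogeneous semi-infinite medium:

* Henyey–Greenstein scattering with anisotropy $g = 0.9$;
  $\mu_s = \mu_s'/(1-g)$.
* Implicit capture: at each step the weight is multiplied by the
  single-scattering albedo, and the absorbed fraction is tallied.
* Fresnel reflection/refraction at the tissue–probe boundary; photons
  exiting within the fiber acceptance cone
  ($\cos\theta \ge \sqrt{1 - (\mathrm{NA}/n_\mathrm{tissue})^2}$)
  are eligible for detection.
* Russian roulette below weight $10^{-4}$ with survival probability 0.1,
  and a 50 cm total-path cap (the exit-path distribution of a
  non-absorbing half-space is heavy-tailed). Both sinks are tallied, so
  the energy ledger `specular + diffuse + absorbed + terminated = 1`
  holds to machine precision — a standing test.
* Detection uses the azimuthal symmetry of the problem exactly: an
  exiting photon at radius $r$ from the source contributes to a detector
  whose center sits at distance $d$ with weight equal to the fraction of
  the circle of radius $r$ lying inside the detector disk,
  $\arccos\!\big((r^2+d^2-a^2)/(2rd)\big)/\pi$. This is a variance
  reduction; it does not change the expectation.
* The kernel uses its own deterministic xoshiro256+ stream seeded from
  `mc_settings(seed=)`, so runs are reproducible and independent of R's
  global RNG.

### White-Monte-Carlo rescaling and the lookup table

A run at $\mu_a = 0$ records, per detected photon, its total path length
$L$, exit radius $r$ and residual weight $w$. For homogeneous
absorption, reweighting each record by $e^{-\mu_a L}$
(`rescale_white_mc()`) reproduces the absorbing-medium reflectance
exactly in expectation. `build_lut()` therefore runs **one** simulation
per $\mu_s'$ node and rescales it across the whole $\mu_a$ grid.

Default grids: $\mu_a \in \{0\} \cup [10^{-3}, 80]$ cm⁻¹ (44 log-spaced
nodes) and $\mu_s' \in [1, 30]$ cm⁻¹ (26 log-spaced nodes). The wide
hull is deliberate: composed spectra reach $\mu_a \approx 0$ at 740 nm
for low-hemoglobin tissue and exceed 60 cm⁻¹ inside the MB dimer band at
the top of the clinical concentration range, while power-law scattering
with amplitude 14 cm⁻¹ and power 1.6 reaches ~29 cm⁻¹ at 500 nm.
Interpolation is bilinear in $(\log(\mu_a + u_0), \log\mu_s')$ of
$\log R$ with $u_0 = 0.01$, which keeps the $\mu_a = 0$ node
representable and is log-like above ~0.1 cm⁻¹; queries outside the hull
raise `drsfit_out_of_range` rather than extrapolating. A grid-refinement
test pins the interpolation error of the production $\mu_a$ grid at
about 1% (worst case) against the exact rescaled value.

```{r}
library(drsfit)
lut <- build_lut(settings = mc_settings(n_photons = 3e4, seed = 5))
```

Problem sizes are the package's own choice: $3 \times 10^4$ photons per
node (≈1 min for the full table on one CPU) is enough because the table's
Monte Carlo noise is smooth across the grid and common to generation and
fitting in the synthetic experiments; production tables for real data
should use `n_photons = 2e5` (the default).

## 2. Chromophores

`chromophore_basis()` carries extinction spectra (cm⁻¹ µM⁻¹, natural-log
convention applied at construction) for oxyhemoglobin, deoxyhemoglobin,
MB monomer and MB dimer on a 450–750 nm grid. The packaged basis is a
**synthetic Gaussian-mixture model**: peak locations (HbO₂ 542/577 nm;
Hb 556 nm, red tail and 758 nm band; MB monomer 664 nm with 614 nm
shoulder; MB dimer 600 nm) and red-region magnitudes follow the standard
literature values, but the detailed shapes are modeled, not measured.
Measured laboratory tables can be supplied as CSVs via
`read_chromophore_basis()` and flow through the whole pipeline
unchanged.

Absorption composes linearly, $\mu_a(\lambda) = \sum_k
\varepsilon_k(\lambda) C_k$; scattering follows the power law
$\mu_s'(\lambda) = a\,(\lambda/665)^{-b}$ so that $a$ *is* the reported
$\mu_s'(665)$. Reporting rules: SO₂ $= 100\,C_\mathrm{HbO_2} /
(C_\mathrm{HbO_2}+C_\mathrm{Hb})$ (undefined, `NA`, at zero total
hemoglobin — never 0); total MB in monomer equivalents
$C_\mathrm{mono} + 2 C_\mathrm{dimer}$.

## 3. Calibration chain

`correct_spectrum()` applies
$R = \dfrac{(\mathrm{raw}-\mathrm{dark})/t_\mathrm{raw}}
           {(\mathrm{cal}-\mathrm{cal_{dark}})/t_\mathrm{cal}}$,
which cancels the lamp–spectrometer system response (verified by a gain
invariance test). Per-wavelength noise is propagated from a shot +
read-noise model; wavelengths where the calibration numerator does not
clear 3× its own noise are masked rather than divided.
`select_integration_time()` implements the adaptive rule
$t_\mathrm{new} = t \cdot \tfrac{1}{2}\mathrm{DR}/\max(\mathrm{raw}-\mathrm{dark})$
clipped to 10–5000 ms, raising `drsfit_saturated` on saturated input.
`detector_qc()` drops fibers with median band SNR below 10 or with more
than 5% of the band above reflectance 1 (loss of contact / specular
contamination) and refuses to proceed with fewer than four usable fibers
(`drsfit_insufficient_fibers`).

## 4. Inversion

`drs_fit()` fits all usable fibers jointly by bound-constrained
Levenberg–Marquardt (`minpack.lm::nls.lm`) over
$(C_\mathrm{HbO_2}, C_\mathrm{Hb}, C_\mathrm{MBmono},
C_\mathrm{MBdimer}, a, b)$, with residuals weighted by the propagated
noise. Pre-administration spectra are fitted with the MB amplitudes
fixed at zero (`mode = "pre"`); `include_dimer = FALSE` reproduces the
dimer-free model variant used for comparison. Spectra that wander outside
the lookup-table hull during the search are clamped with a smooth
penalty.

Robustness against local minima comes from three layers:

1. eight Latin-hypercube starts over the clinically plausible sub-box,
   plus a linearized hemoglobin start from two wavelengths bracketing the
   Hb/HbO₂ crossover;
2. best-of-all-starts selection by residual sum of squares;
3. a *refinement wave* triggered only when the best solution still
   misfits the data by far more than the noise allows (weighted mean
   square > 10, i.e. ~3σ per point): a second Latin hypercube over the
   full bound box plus jittered copies of the interim best. The trigger
   is data-internal, so it cannot mask genuine misfit.

The quality metric SRSE (sum over fibers of the root of the per-fiber
squared-error sum) is reported alongside the optimizer's weighted SSR;
both readings of the formula are available (`fit_config(srse=)`).

## 5. Synthetic data generator — and its realism limits

`cohort_spec()` / `sample_cohort()` draw paired pre/post ground truths
with ranges anchored to the clinical cohort (pre $\mu_{a,665}$
log-uniform in 0.03–0.36 cm⁻¹, $\mu_s'$ 4.8–13.2 cm⁻¹, SO₂ 5.6–100%,
MB log-uniform 0.1–311 µM with a 2/13 point mass at zero). Effect rules
emulate the observed trends: the dimer fraction rises with total MB
($f_d = 0.7\,\mathrm{MB}/(\mathrm{MB}+30)$), SO₂ falls with uptake, and
scattering decreases after administration. `simulate_measurement()`
pushes the truth through the *inverse* of the calibration chain — system
response, adaptive integration time, dark offsets, shot-shaped noise
scaled to a target median SNR plus read noise — and emits raw
sample/dark/calibration spectra, so the analysis path for synthetic data
is byte-identical to the real-data path. Contact failures are injected as
either specular contamination or signal loss.

Realism limits, stated plainly: the medium is homogeneous and
semi-infinite (no abscess-wall layering or cavity geometry), the
extinction basis is synthetic, noise is Gaussian with a shot-shaped
variance (no detector nonlinearity, wavelength calibration error, or
fiber-to-fiber throughput variation), and the same lookup table generates
and fits the synthetic spectra, so recovery errors reflect noise
propagation through the inversion, not model mismatch. Recovery RMSEs
from this generator are therefore optimistic relative to real tissue.

## 6. Validation and statistics

The test suite validates the physics against independent oracles: exact
energy conservation; white-rescaling vs direct absorbing runs within 3×
combined standard error at $\mu_a \in \{0.1, 1, 10, 50\}$ cm⁻¹; and the
Farrell–Patterson–Wilson diffusion formula within 15% at 3–6 mm
separations for $\mu_s' \gg \mu_a$ (diffusion theory is itself marginal
at the probe's sub-millimeter separations, which is why a Monte Carlo
forward model is used at all). Noise-free round trips recover parameters
to better than 2%; at SNR 100 the MB and $\mu_s'(665)$ recovery RMSEs
over cohort-range sweeps sit well inside the instrument-validation
bounds of 0.52 µM and 2.7 cm⁻¹.

`cohort_report()` reproduces the cohort-level analysis: mean ± SD
summaries, paired Wilcoxon signed-rank tests (exact null by convolution
over doubled midranks up to n = 25, zero differences dropped, tie- and
continuity-corrected normal approximation above), Spearman correlation
of MB uptake against the SO₂ change, and Mann–Whitney / Kruskal–Wallis
with Dunn's pairwise z-tests for group comparisons.

```{r}
report <- cohort_report(abscess_cohort())
print(report)
```
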