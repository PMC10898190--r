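Package: drsfit
Title: Diffuse Reflectance Spectroscopy of Abscess Cavities: Monte Carlo
    Forward Modeling and Chromophore Inversion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for spatially resolved diffuse reflectance
    spectroscopy with a multi-fiber contact probe, aimed at quantifying
    abscess-wall optical properties and methylene blue uptake prior to
    photodynamic therapy.  Provides a photon Monte Carlo forward model for
    a semi-infinite medium with white-Monte-Carlo rescaling and a
    reflectance lookup table; spectrometer calibration corrections and
    detector-fiber quality control; bound-constrained multispectral
    inversion for oxy/deoxy-hemoglobin and methylene blue monomer/dimer
    concentrations plus power-law reduced scattering; a synthetic
    clinical-like measurement generator with known ground truth; and
    nonparametric cohort summaries and tests (exact Wilcoxon signed-rank,
    Spearman correlation, Mann-Whitney, Kruskal-Wallis with Dunn's test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    lhs,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
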