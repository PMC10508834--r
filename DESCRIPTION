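Package: pulmtree
Title: Multiscale Pulmonary Arterial-Venous Hemodynamics with Structured-Tree
    Microvascular Beds and Polynomial-Chaos Uncertainty Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pulse-wave propagation in the proximal pulmonary arteries
    and veins with a nonlinear one-dimensional solver (two-step Lax-Wendroff),
    coupled through two-sided structured-tree models of the microvascular beds
    via frequency-domain grand admittance and time-domain convolution boundary
    conditions. Computes mechanobiological quantities of interest (wall shear
    stress, cyclic stretch), wave-intensity analysis with four-type wave
    classification, and distal alpha/beta-pathway hemodynamics. Includes a
    Legendre polynomial-chaos expansion surrogate pipeline with ordinary
    least-squares fitting, validation error, and first-order, total-order and
    generalized Sobol' sensitivity indices, plus generators for synthetic
    boundary waveforms (single-peak pulmonary inflow, two-peak left-atrial
    pressure).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    lhs,
    jsonlite,
    generics,
    withr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
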