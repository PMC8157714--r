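Package: cavitydiff
Title: Water Transport in Viscous Saccharide Matrices by Cavity Hopping
Version: 0.1.0
Authors@R: person("Aerosol", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying water transport in viscous aqueous-organic
    (saccharide) matrices. Provides a spherical-shell Fickian model of droplet
    size response to relative-humidity steps and inverse fitting of the
    composition-dependent water diffusion coefficient D_w(a_w); stretched
    exponential (KWW) characterization of response functions; Stokes-Einstein
    prediction, fractional-exponent fitting and divergence quantification
    against an independent viscosity axis; molecular-trajectory analysis of the
    cavity-hopping transport mechanism (MSD diffusion coefficients, Gaussian
    hidden Markov state models with relaxation timescales, Boltzmann-inversion
    potentials of mean force, transition-state-theory barriers and hop
    statistics); grid-based free-volume fractions of packed configurations; and
    synthetic-data generators with known ground truth for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
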