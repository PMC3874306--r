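Package: wavesel
Title: Genetic-Algorithm Wrapper Selection of Spectral Variables with
    Support Vector Machine Fitness
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Wrapper feature selection for spectroscopic classification.
    A variable-length genetic algorithm searches subsets of wavelength
    indices; each candidate subset is scored by training one-vs-rest
    soft-margin support vector machines on the projected spectra and
    summing per-class misclassification mean squared errors. Includes a
    deterministic SMO solver with linear, Gaussian and polynomial
    kernels, a random hyperparameter search over (C, epsilon, sigma),
    strict one-vs-rest error accounting, a synthetic mid-infrared
    spectrum generator with planted informative wavelengths, and a
    command-line workflow (generate / optimize / select / evaluate).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
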