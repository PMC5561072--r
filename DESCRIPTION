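Package: dfspoly
Title: Polymer-Linked Dynamic Force Spectroscopy of Molecule-Surface Bonds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts bond kinetics (intrinsic unbinding rate, distance to the
    transition state), the equilibrium rupture force, and the per-monomer
    binding free energy from dynamic force spectroscopy experiments in which
    the probed bond is loaded through a flexible polymer tether. Provides
    worm-like-chain force-extension mechanics, the Bell-Evans single-bond
    mean-rupture-force model with a numerically stable exponential-integral
    kernel, a Monte Carlo first-passage rupture simulator, a force-curve
    processing pipeline (rupture detection, last-event worm-like-chain
    fitting, apparent-persistence-length filtering, velocity-grouped mean
    spectra), and a ground-truthed synthetic force-curve generator for
    validating every stage without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
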