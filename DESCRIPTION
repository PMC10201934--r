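Package: cerstep
Title: Cerenkov Photon Emission and Transport with Step-Limited Electron Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale Monte Carlo simulation of Cerenkov photon production by
    photoelectric recoil electrons in dense scintillators (BGO, TlBr) and of the
    optical photon transport to a front-coupled photodetector. Electrons are
    tracked step by step with analytic Berger-Seltzer stopping-power and CSDA
    range tables; the step length can be limited by a maximum fractional change
    of the relativistic velocity per step (delta-beta), the parameterization
    that controls how well the tortuous electron path is resolved. Cerenkov
    yields follow the Frank-Tamm formula integrated over a tabulated
    refractive-index dispersion, photons are emitted on the Cerenkov cone and
    ray-traced through a wrapped crystal with Fresnel surface optics. Analysis
    helpers reproduce step-length statistics, Gaussian-fit photon counts,
    order-resolved angular distributions and detection-time histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
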