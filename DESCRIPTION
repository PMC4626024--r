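Package: pemtrack
Title: Diffusive-State Mixture Analysis of Single-Particle Trajectories by
    Perturbation Expectation-Maximization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Uncovers the number and properties of normal diffusive states
    (diffusivity, static localization noise, population fraction) from large
    collections of short, noisy two-dimensional single-particle trajectories,
    such as those produced by sptPALM imaging of membrane proteins. The core
    is a Gaussian mixture model over per-trajectory displacement vectors whose
    state covariances account for static localization noise and motion blur,
    maximized by expectation-maximization with Monte-Carlo bootstrap
    perturbations of the likelihood surface to escape local maxima, and model
    size selected by a Bayesian information criterion sweep. Includes a
    trajectory simulator with motion blur and static noise, covariance-based
    (CVE) single-track estimators, posterior-based trajectory classification,
    and a cumulative-distribution-of-squared-displacements baseline fitter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    minpack.lm,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
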