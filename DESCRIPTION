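Package: anlv
Title: Attenuated Nonlinear Viscoelastic Models of Passive Extraocular Muscle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, diagnostics and system identification for passive
    extraocular-muscle force models. Implements Fung's quasi-linear
    viscoelastic (QLV) model, the adaptive QLV (AQLV) model with
    length-dependent process stiffness, and their attenuated nonlinear
    viscoelastic (ANLV) extension in which a thixotropy-style structural
    parameter breaks down under imposed elongation and scales each
    viscoelastic process by its own gain. Provides generators for the
    standard elongation protocols (quick steps, saccade-like half-sinusoid
    elongations, constant-speed ramps, double-elongation sequences),
    an exact-exponential state-space integrator, phenomenological
    diagnostics (dynamic force, data/model viscoelastic ratio, relaxation
    cross-over and convergence), synthetic noisy recordings, and an elitist
    genetic-algorithm fitter with quasi-random seeding for the attenuation
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
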