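Package: reachfield
Title: Encoding Models and Selectivity Analysis for Reach-Planning Neurons
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse how reach direction and amplitude modulate the
    spiking activity of motor-planning neurons recorded in center-out
    memory-reach tasks. Provides a synthetic generator of Poisson-spiking
    neurons with known ground-truth tuning, task-relatedness and
    direction/amplitude selectivity screening (two-way fixed-effect ANOVA,
    direction-wise t-tests, shuffle nulls, binomial proportion tests),
    preferred-direction circular statistics (Rayleigh test, circular mean
    and standard error, delta-PD), spatial response-field characterization
    (scattered linear interpolation onto a Cartesian grid, peak eccentricity
    and field width in visual degrees), and cross-validated comparison of
    five parametric encoding models (cosine and Von Mises directional tuning
    with optional linear amplitude gain, and a 2D Gaussian position model)
    against a split-half noise ceiling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
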