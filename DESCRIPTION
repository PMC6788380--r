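Package: gaitdyn
Title: Latent Neural Dynamics and Kinematic Decoding During Locomotion
Version: 0.1.0
Authors@R:
    person("gaitdyn", "maintainers", email = "gaitdyn@example.org", role = c("aut", "cre"))
Description: Tools for analysing low-dimensional motor-cortex population dynamics
    during locomotion. Fits Poisson linear dynamical system (PLDS) models to
    spike-count data with Laplace-approximated EM, decodes hind-limb kinematics
    and gait-cycle phase with lagged linear (Wiener) filters from competing
    neural feature sets (full population, PLDS latents, PCA components, greedy
    predictive neuron subsets), characterises gait-cycle-normalized latent
    trajectory geometry with Mahalanobis distance profiles, and compares decoder
    output smoothness with multitaper spectral estimates. Includes a synthetic
    locomotor-session generator with known ground truth so the full pipeline is
    testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
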