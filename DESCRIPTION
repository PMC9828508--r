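Package: atomgpr
Title: Atomic Gaussian Process Regression Potentials by Active Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds per-atom Gaussian process regression (kriging) models of
    atomic energies from molecular trajectories, using translation- and
    rotation-invariant atomic local frame (ALF) features with a cyclic
    squared-exponential kernel. Hyperparameters are trained by particle swarm
    optimization of the marginal log-likelihood, and training sets are grown by
    maximum expected prediction error (MEPE) active learning with per-atom or
    per-system acquisition and multi-point batches. Includes a synthetic
    normal-mode-style configuration sampler and a toy potential energy surface
    with an exact per-atom energy partition, plus model-quality reporting
    (S-curves, learning curves, true-versus-predicted tables, Kabsch
    superposition).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
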