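Package: alchemr
Title: Ensemble Alchemical Free-Energy Estimation and Uncertainty Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis stack for relative binding free-energy calculations from
    alchemical sampling. Implements ensemble thermodynamic integration (TIES)
    with bootstrap error propagation, a self-consistent MBAR solver with the
    asymptotic covariance estimator, BAR and Zwanzig exponential averaging,
    phase-space overlap diagnostics with the tridiagonal 0.03 criterion,
    soft-core Lennard-Jones lambda scaling, and the comparison and
    distribution-shape statistics used to benchmark estimators and engines.
    Synthetic generators (Gaussian chains with closed-form free energies,
    slow mode-switching mixtures, a Metropolis-sampled toy Lennard-Jones
    particle) provide analytically known references in place of molecular
    dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    withr
Config/testthat/edition: 3
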