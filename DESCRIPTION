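Package: bsdr
Title: Bayesian Spectral Decomposition of Neural Power Spectra
Version: 0.1.0
Authors@R:
    person("BSDR", "Developers", email = "bsdr@example.org", role = c("aut", "cre"))
Description: Specification, variational Bayesian inversion, comparison and
    group-level analysis of parametric models of neural power spectra. Spectra
    are modelled as a power-law aperiodic component plus band-limited Gaussian
    peaks; models are inverted with variational Laplace to obtain Gaussian
    parameter posteriors and a free-energy approximation of the log model
    evidence, candidate peaks are detected by Bayes-factor model comparison,
    and covariate effects across subjects are estimated with parametric
    empirical Bayes. Includes seeded simulation generators for face-validity
    and detection-benchmark studies and ROC/AUC evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
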