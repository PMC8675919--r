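Package: odorddm
Title: Drift-Diffusion Analysis of Odor Detection in Background Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-alternative odor-detection behaviour with
    the drift-diffusion model (DDM). Provides closed-form choice probabilities,
    mean decision times and their parameter derivatives; defective
    first-passage-time distributions of the Wiener process between two
    absorbing thresholds; prediction curves for three hypothesised mechanisms
    by which background odorants interfere with target detection (false
    signal, signal reduction, noise boost); a stochastic trial simulator and a
    synthetic generator for the adaptive mouse target-detection task;
    session-level preprocessing; chi-square quantile fitting of per-condition
    drift and diffusion from trial-level choice and reaction-time data; and
    posterior-predictive and parameter-recovery diagnostics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
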