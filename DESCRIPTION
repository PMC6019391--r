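Package: raceSAT
Title: Two-Accumulator Race Models of the Speed-Accuracy Tradeoff with
    Neurodynamic Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, fitting and neural-signal prediction for a
    two-accumulator rectified race model of perceptual decisions under
    speed/accuracy instructions. Fits model variants to reaction-time
    distributions by quantile maximum probability estimation with a
    differential-evolution optimizer, re-expresses fitted parameters under a
    forced-excursion (fixed baseline-to-boundary distance) constraint, and
    predicts two neurodynamic read-outs of the decision variable: a
    kernel-smoothed motor-evoked-potential difference signal sampled at
    simulated stimulation times, and a centroparietal ERP-like signal formed
    from censored averages of summed accumulators. Includes the bespoke
    statistics used to compare model variants against neural profiles:
    slope permutation tests, cluster-based amplitude tests with BCa
    bootstrap bands, and bias-corrected bootstrap intervals on
    mean-squared-error differences. A synthetic-data module generates
    complete studies (trial tables, stimulation schedules, MEP records,
    ERP-like epochs) with known ground truth.
License: MIT + file LICENSE
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
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
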