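Package: ppghrv
Title: Heart-Rate Variability and Pulse-Wave Morphology from Wrist PPG
Version: 0.1.0
Authors@R: person("Maxima", "Devel", email = "devel@example.org", role = c("aut", "cre"))
Description: Tools for analysing continuous wrist photoplethysmography (PPG)
    recordings around a pharmacological intervention: trough-based inter-pulse
    interval (IPI) extraction with physiological-range and successive-difference
    artifact rejection, cubic-spline gap filling, time-domain, frequency-domain
    and non-linear heart-rate-variability features, second-derivative pulse-wave
    morphology features, per-day ensemble-average pulses, and a non-parametric
    comparison layer (Friedman and Kruskal-Wallis omnibus tests, Dunn post hoc
    contrasts with Bonferroni correction, bootstrap Cohen's d effect sizes).
    Includes a synthetic multi-day PPG cohort generator with known ground truth
    so the full pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
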