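Package: ttcal
Title: T-Type Channel Gating, Egg-Laying Interval Models, and GCaMP Trace
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analyses for studies of T-type calcium-channel
    gating of peptidergic inhibition in C. elegans egg-laying behavior.
    Implements the two-state stochastic model of inter-egg-laying intervals
    (a two-exponential mixture CDF fitted by nonlinear least squares),
    steady-state biophysics of voltage-clamped low-voltage-activated
    channels (Goldman-Hodgkin-Katz chord conductances, Boltzmann
    activation/inactivation fits, window-current curves and metrics,
    oocyte leak QC), the GCaMP fluorescence pipeline (background
    subtraction, linear photobleach baseline, dF/F, and the cumulative
    dF/F total-variation statistic), ordinal embryo-stage summaries with
    exact Wilcoxon-Mann-Whitney rank-sum tests, and seeded synthetic-data
    generators emulating every input so all results are reproducible
    without bench data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
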