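Package: cghofd
Title: Cuffless Blood Pressure Estimation by Gaussian-Process Hybrid Optimal Feature Decision
Version: 0.1.0
Authors@R:
    person("CGHOFD", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for cuffless blood-pressure estimation from synchronized
    ECG, finger-PPG and arterial-pressure waveforms. Implements the full
    chain: seeded synthetic waveform and feature-table generators, Kaiser
    FIR denoising and 20-second segmentation with amplitude and blood
    pressure gating, fiducial-point detection and extraction of 25 pulse
    morphology and timing features, three interchangeable feature-weighting
    filters (one-way-ANOVA F-test, robust neighborhood component analysis,
    and minimum-redundancy-maximum-relevance ranking), Gaussian-process
    regression with a squared-exponential kernel and explicit basis, and a
    wrapper (hybrid optimal feature decision) that shrinks the weight-ranked
    feature list to the subset minimizing cross-validated RMSE. Evaluation
    follows the AAMI and BHS device protocols (ME/SDE, MAE, RMSE, R-squared,
    cumulative error grading, Bland-Altman statistics, one-way ANOVA
    comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
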