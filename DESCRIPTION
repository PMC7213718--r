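Package: cardiofit
Title: Genetic-Algorithm Personalization of Human Ventricular
    Action-Potential Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the conductance and flux parameters of the O'Hara-Rudy
    (2011) human ventricular myocyte model to steady-state action-potential
    waveforms recorded at several pacing cycle lengths. The optimizer is a
    modified real-coded genetic algorithm with simulated binary crossover,
    Cauchy mutation along a random direction in parameter space, a large
    elite fraction, per-organism state persistence, and slow intracellular
    concentrations ([Na+]i, [Ca2+]NSR) included as genes so that the fitted
    model is itself at pacing steady state. Includes an adaptive
    Rush-Larsen integrator for the single cell and a 1D cable,
    an optical-mapping-aware fitness function (time alignment, affine
    renormalization, upstroke masking), signal conditioning utilities
    (60 Hz notch, ensemble averaging, calibrated noise injection),
    PCA-based convergence diagnostics, and rescaling of fitted parameters
    between subjects by mRNA expression ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
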