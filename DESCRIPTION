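Package: clockwave
Title: Waveform-Dependent Period Variability in Circadian Clock Outputs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the waveform of clock-to-output
    regulation shapes the period variability of circadian output rhythms.
    Provides Euler-Maruyama simulation of a noisy Goodwin
    transcriptional-translational feedback loop and of a phase-oscillator
    clock, each coupled to a linear reporter system; peak- and
    threshold-based period statistics (coefficient of variation of the
    cycle-to-cycle period); a closed-form decomposition of the output
    period CV into phase-variance, amplitude-autocorrelation and
    cross-correlation components; and samplers over Fourier-coefficient
    space (uniform random scans, grid-conditional Gibbs sampling with
    exp(-CV) weighting, and evolutionary minimisation) that probe which
    regulatory waveforms minimise output period fluctuations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
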