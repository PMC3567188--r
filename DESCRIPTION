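Package: stdpdelay
Title: Delay Selection by Spike-Timing-Dependent Plasticity in
    Oscillation-Driven Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytical theory and spiking simulations of conduction-delay
    selection by additive spike-timing-dependent plasticity (STDP) in
    recurrent networks driven by sinusoidally modulated Poisson inputs.
    Provides closed-form Fourier transforms of double-exponential EPSP
    kernels and bimodal exponential learning windows, Fourier-domain
    predictions of which axonal (and dendritic) delays are potentiated for
    a given input modulation frequency, bounded evolution of weighted delay
    profiles about a homeostatic mean, post-learning oscillatory response
    amplitudes for single and two-group networks, an oscillatory
    inhomogeneous-Poisson spike-train generator with correlogram
    estimation, and a delay-aware Poisson/leaky integrate-and-fire network
    simulator with online STDP.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
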