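Package: fhnsmr
Title: Stochastic Multiresonance in Delay-Coupled FitzHugh-Nagumo Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and information-theoretic analysis of stochastic
    multiresonance in small-world networks of noise-driven, delay-coupled
    FitzHugh-Nagumo neurons. Provides an explicit Euler-Maruyama integrator
    for the delayed network model, mean-field spike and inter-spike-interval
    extraction, Bandt-Pompe ordinal-pattern probability distributions with
    the normalized Shannon entropy and Jensen-Shannon statistical complexity
    measure, periodogram-based signal-to-noise ratio estimation, surrogate
    interval-series generators, and resonance-curve sweep protocols over
    noise intensity, transmission delay, and network parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
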