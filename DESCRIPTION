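Package: microbump
Title: Stochastic Quantum-Bump Simulation and Noise Analysis for
    Rhabdomeric Photoreceptors
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the stochastic phototransduction cascade of a single
    photoreceptor microvillus (G-protein activation, PLC, DAG accumulation
    and TRP channel gating) to produce elementary current responses
    ("quantum bumps"), extracts per-bump features and ensemble statistics,
    sweeps the main cascade activation parameters, builds multiphoton
    composite responses, models flicker frequency responses and 3 dB
    corner frequencies, quantifies transduction and photon (Poisson) noise
    with an area-based signal-to-noise ratio, maps Shannon-Hartley
    information capacity over bump duration and latency dispersion, and
    implements a five-stage algorithm that recovers quantum-bump
    statistics from macroscopic impulse responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
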