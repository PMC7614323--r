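Package: ditherstim
Title: Dithered Brain Stimulation and Selective Neural Entrainment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for selective entrainment of
    neural oscillators by dithered (noisy-period) brain stimulation.
    Provides deterministic and stochastic sine circle map simulators,
    populations of coupled noisy Kuramoto phase oscillators driven by
    charge-balanced biphasic pulse trains, closed-form Arnold tongue
    theory for p:1 and (2p-1):2 frequency locking under period
    dithering, pulse train generators including device-implementable
    frequency-set cycling schemes, entrainment metrics (rotation number,
    plateau-based locking detection, tongue widths, mean instantaneous
    frequency, phase locking value), and reproducible parameter sweep
    orchestration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
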