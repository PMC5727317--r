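Package: kaiabc
Title: Multifold-Feedback Simulator of the KaiABC Circadian Oscillator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Hybrid deterministic-stochastic simulator of the in vitro
    KaiABC circadian clock. Each KaiC hexamer carries a 29-state
    probability distribution over KaiA/KaiB binding configurations
    (master-equation ODEs under a factorized, Hartree-like
    approximation), a continuous phosphorylation level confined by a
    soft-spin potential, and an allosteric structural order parameter
    obtained as a quasi-equilibrium mean-field average. Stochastic
    ATP-hydrolysis (Pi-release) events on the CI ring perturb the
    structure and drive the ensemble-level oscillation; hexamers are
    coupled only through shared free KaiA and KaiB concentrations
    (KaiA sequestration). Includes analysis tools for oscillation
    amplitude and FFT-based period estimation, parameter sweeps,
    phase diagrams over KaiA/KaiB concentrations, and the correlation
    between ATPase activity and phosphorylation-rhythm frequency.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
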