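Package: fabkin
Title: Kinetic and Thermodynamic Analysis of Antibody Charge Variants by SPR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing surface plasmon resonance (SPR) binding
    experiments on antibody fragments (Fabs) and their charge-engineered
    variants. Simulates and globally fits 1:1 Langmuir sensorgrams across a
    concentration series, derives equilibrium thermodynamics (Gibbs energy
    from Kd, nonlinear van't Hoff analysis with a heat-capacity term) and
    transition-state parameters (Eyring analysis of the association rate),
    extracts melting temperatures from two-state DSC thermograms, and
    computes net charge and isoelectric point of mutant light-chain
    sequences under the Henderson-Hasselbalch approximation. Includes a
    thermodynamically self-consistent synthetic-experiment generator so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
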