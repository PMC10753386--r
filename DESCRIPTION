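Package: apqr
Title: Closed-Loop Optogenetic Control of Cardiac Action Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation of opto-electronic feedback control of the cardiac
    membrane potential. Provides a synthetic optogenetic cardiomyocyte
    monolayer (a phenomenological excitable-membrane model with a blue-light
    gated depolarizing conductance and a red-light driven hyperpolarizing
    pump current), three tick-level closed-loop controllers (an adaptive
    proportional controller, a PID controller with a regression-based
    derivative, and a waveform-enforcement controller with optical pacing),
    a fixed-step 1-kHz loop engine implementing drug- and light-perturbation
    protocols, triangular and recorded model action-potential waveforms, and
    the quantification used to judge control quality (action-potential
    durations, membrane-potential error traces, binned error distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
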